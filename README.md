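# istqc — quality control metrics for imaging spatial transcriptomics

Imaging-based spatial transcriptomics (iST) platforms — Molecular
Cartography, Merscope, Xenium — decode individual RNA molecules in situ
and report a table of gene identities with micrometre coordinates.
Choosing between platforms, or judging whether a run is trustworthy,
requires metrics that work across vendors. `istqc` implements a
technology-agnostic QC suite for analysts benchmarking such platforms:

* **Sensitivity** — transcript/feature counts in square spatial bins
  whose area equals a sequencing-platform capture spot (side
  `(d/2)·√π`, i.e. 48.74 µm for a 55 µm spot), per-cell medians with
  bootstrap standard errors, cross-platform per-gene mean correlation
  on `log10(mean + c)`, and detection-efficiency anchoring
  (`fold × reference efficiency`).
* **Specificity** — built on the vendors' background probes (controls
  with no target in the sample): probe count ranking against the
  background range; the global segmentation-free false discovery rate

  ```
  FDR(%) = (background calls / n background probes)
         × (n target genes / total target calls) × 100
  ```

  Moran's I spatial autocorrelation of per-cell counts with
  inverse-distance weights `w_ij = 1/d_ij` (no row standardisation),
  min–max scaled per dataset; per-probe median nearest-neighbour
  distances; and a stratified 0.95-quantile classifier that flags
  targets that are both within the background count range *and* as
  spatially diffuse as the background — while rescuing low-count but
  clustered markers of rare cell types.
* **Optical metrics** — bead resolution as median ± MAD of
  full-width-at-half-maximum measurements through detected local
  maxima; spot `SNR = (I(0) − µ_bg)/σ_bg` and `SBR = I(0)/µ_bg` on
  dark-subtracted 21-sample line profiles.
* **Stitch-border deduplication** — consensus-shift removal of
  duplicate transcripts straddling tile-grid lines.
* **Neighbourhood enrichment** — z-scores and permutation p-values
  (Benjamini–Hochberg adjusted) for cell-type pairs on the 10-NN graph
  of cell centroids.
* **Synthetic data** — a generator for two-compartment tumor-like
  tissues, bead stacks, spot profiles and planted stitch duplicates
  with known ground truth, so every metric is testable offline.

## Worked example

Simulate a 1 mm² two-compartment tissue (1,500 cells, detection
efficiency 0.35, ten background probes), assign transcripts to nuclei
and compute the core metrics:

```r
library(istqc)

sim <- simulate_tissue(tissue_sim_config(seed = 42L))
asg <- assign_transcripts(sim$transcripts, sim$mask, sim$panel)
asg$stats
#>   n_total n_assigned assigned_fraction
#> 1   58098      55236         0.9507384

per_cell_summary(asg$matrix, seed = 42L)
#>   median_transcripts se_transcripts median_features se_features n_cells n_genes_used
#> 1                 39      0.6326927               3   0.3711678    1500            9

global_fdr(sim$transcripts, sim$panel)
#>   fdr_percent background_barcode_calls number_of_background_barcodes
#> 1    5.062541                     3094                            10
#>   number_of_target_genes total_target_gene_calls
#> 1                      9                   55004

st <- specificity_table(sim$transcripts, sim$panel, sim$mask)
sum(st$within_background_range); sum(st$low_confidence)
#> [1] 1
#> [1] 0
st[st$gene_id == "CD19", c("total_count", "median_nn_distance", "low_confidence")]
#>   total_count median_nn_distance low_confidence
#> 9         103           1.218361          FALSE
```

Reading the output: 95% of molecules fall inside segmented nuclei; the
median cell carries 39 detected transcripts over 3 of the 9 panel
genes; the background probes imply a global FDR of 5.1%. The rare-cell
marker CD19 has a background-level total (103 calls, within the
background count range) but a median nearest-neighbour distance of
1.2 µm — its calls are packed inside scattered single cells, twenty
times tighter than the ~25–35 µm spacing of the spatially random
background probes — so the classifier does **not** flag it: exactly the
low-abundance-but-real signal the spatial metrics exist to rescue.

Binning instead of segmenting (`bin_counts(sim$transcripts,
visium_bin_side(55))`) yields 441 spot-equivalent bins with a median of
122 transcripts each.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "stqc.R", package = "istqc"))')" \
    simulate --out sim_out --seed 42
```

with subcommands `simulate`, `sensitivity`, `specificity`, `dedup`,
`neighborhood`, `report`.

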