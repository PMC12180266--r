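Package: istqc
Title: Quality Control Metrics for Imaging-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A technology-agnostic toolkit for benchmarking imaging-based
    spatial transcriptomics (iST) platforms such as Molecular Cartography,
    Merscope and Xenium. Implements segmentation-free and per-cell
    sensitivity metrics (spatial binning at Visium-spot-equivalent area,
    per-cell transcript and feature medians, cross-platform gene-mean
    correlation, detection-efficiency anchoring), background-probe
    specificity metrics (global false discovery rate, inverse-distance
    Moran's I spatial autocorrelation, nearest-neighbor distances,
    percentile-based probe confidence classification, nuclear fraction,
    z-plane truncation diagnostics), optical metrics (bead full width at
    half maximum with median absolute deviation, spot signal-to-noise and
    signal-to-background ratios), stitch-border transcript deduplication,
    and permutation-based cell-type neighborhood enrichment. A synthetic
    data module generates tissues, probe panels, bead stacks, spot
    profiles and planted stitch artifacts with known ground truth so that
    every metric is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Matrix,
    methods,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    arrow,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
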