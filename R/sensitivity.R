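#' Side of the square bin matching a circular Visium spot
#'
#' Imaging platforms are compared to sequencing-based spots segmentation-free
#' by counting transcripts in square bins whose area equals that of one
#' circular capture spot: side `= (d / 2) * sqrt(pi)`, so
#' `side^2 = pi * (d/2)^2` to machine precision. For the standard 55 um
#' spot this is 48.74 um (2375.8 um^2).
#'
#' @param spot_diameter spot diameter in micrometres (>= 0).
#' @return The bin side length in micrometres.
#' @export
visium_bin_side <- function(spot_diameter) {
  if (!is.numeric(spot_diameter) || any(spot_diameter < 0)) {
    stop_istqc("`spot_diameter` must be >= 0")
  }
  spot_diameter / 2 * sqrt(pi)
}

#' Bin transcripts on a square grid
#'
#' Counts transcripts (optionally restricted to a gene subset) in
#' half-open square bins of the given side. The grid is anchored at the
#' minimum of the transcript bounding box, which makes the binning
#' deterministic and data-driven; all bins inside the bounding box are
#' retained, including empty ones. Features are genes with count > 0 in a
#' bin.
#'
#' @param tt a [transcript_table()].
#' @param side bin side length in micrometres (> 0).
#' @param genes optional character vector restricting the gene set.
#' @return A `bin_grid`: list with `origin`, `side`, `nx`, `ny`, `bins`
#'   (data.frame `bin_x`, `bin_y`, `total`, `features`) and a sparse
#'   bins x genes count matrix `counts`.
#' @export
bin_counts <- function(tt, side, genes = NULL) {
  assert_scalar_number(side, "side", lower = 0, strict_lower = TRUE)
  if (!is.null(genes)) {
    tt <- tt[tt$gene %in% genes, , drop = FALSE]
  }
  if (nrow(tt) == 0L) {
    return(structure(list(
      origin = c(NA_real_, NA_real_), side = side, nx = 0L, ny = 0L,
      bins = data.frame(bin_x = integer(), bin_y = integer(),
                        total = integer(), features = integer()),
      counts = Matrix::sparseMatrix(i = integer(), j = integer(),
                                    x = numeric(), dims = c(0L, 0L))
    ), class = "bin_grid"))
  }
  origin <- c(min(tt$x), min(tt$y))
  ix <- floor((tt$x - origin[1]) / side)
  iy <- floor((tt$y - origin[2]) / side)
  nx <- max(ix) + 1L
  ny <- max(iy) + 1L
  bin <- iy * nx + ix + 1L
  gene_levels <- sort(unique(tt$gene))
  counts <- Matrix::sparseMatrix(
    i = bin, j = match(tt$gene, gene_levels), x = rep(1, nrow(tt)),
    dims = c(nx * ny, length(gene_levels)),
    dimnames = list(NULL, gene_levels)
  )
  all_bins <- seq_len(nx * ny)
  bins <- data.frame(
    bin_x = (all_bins - 1L) %% nx,
    bin_y = (all_bins - 1L) %/% nx,
    total = as.integer(Matrix::rowSums(counts)),
    features = as.integer(Matrix::rowSums(counts > 0))
  )
  structure(list(origin = origin, side = side, nx = nx, ny = ny,
                 bins = bins, counts = counts),
            class = "bin_grid")
}

#' Per-cell sensitivity summary
#'
#' Median transcripts per cell and median features (genes with count > 0)
#' per cell over a gene subset, with bootstrap standard errors of the
#' medians (the conventional way to attach uncertainty to a median when no
#' closed form is assumed).
#'
#' @param m a [cell_by_gene()].
#' @param genes optional gene subset (defaults to all columns).
#' @param n_boot bootstrap replicates for the standard errors.
#' @param seed bootstrap seed.
#' @return A one-row data.frame: `median_transcripts`, `se_transcripts`,
#'   `median_features`, `se_features`, `n_cells`, `n_genes_used`.
#' @export
per_cell_summary <- function(m, genes = NULL, n_boot = 1000L, seed = 1L) {
  counts <- m$counts
  if (nrow(counts) == 0L) stop_istqc("matrix has no cells")
  if (!is.null(genes)) {
    keep <- intersect(genes, colnames(counts))
    counts <- counts[, keep, drop = FALSE]
  }
  tx <- as.numeric(Matrix::rowSums(counts))
  ft <- as.numeric(Matrix::rowSums(counts > 0))
  boot_se <- function(v) {
    if (length(v) < 2L) return(0)
    reps <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        stats::median(v[sample.int(length(v), replace = TRUE)])
      }, 0)
    })
    stats::sd(reps)
  }
  data.frame(
    median_transcripts = stats::median(tx),
    se_transcripts = boot_se(tx),
    median_features = stats::median(ft),
    se_features = boot_se(ft),
    n_cells = nrow(counts),
    n_genes_used = ncol(counts)
  )
}

#' Cross-platform per-gene mean correlation
#'
#' For each shared gene, the mean transcript count per cell is computed in
#' both matrices; the Pearson correlation of `log10(mean + pseudocount)`
#' across genes measures how consistently the two platforms rank and scale
#' gene abundance. The log transform keeps lowly expressed genes from
#' being swamped by abundant ones; the per-gene table supports plotting
#' against the identity line.
#'
#' @param mA,mB two [cell_by_gene()] matrices.
#' @param genes optional shared gene subset (defaults to the column
#'   intersection).
#' @param pseudocount added before the log10 transform.
#' @return list with `r` (Pearson coefficient) and `per_gene`
#'   (data.frame `gene`, `mean_a`, `mean_b`).
#' @export
gene_mean_correlation <- function(mA, mB, genes = NULL, pseudocount = 0.01) {
  shared <- intersect(colnames(mA$counts), colnames(mB$counts))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3L) {
    stop_istqc("need at least 3 shared genes")
  }
  mean_a <- as.numeric(Matrix::colSums(mA$counts[, shared, drop = FALSE])) /
    nrow(mA$counts)
  mean_b <- as.numeric(Matrix::colSums(mB$counts[, shared, drop = FALSE])) /
    nrow(mB$counts)
  la <- log10(mean_a + pseudocount)
  lb <- log10(mean_b + pseudocount)
  if (stats::var(la) == 0 || stats::var(lb) == 0) {
    stop_istqc("zero variance after transform; correlation undefined")
  }
  list(r = stats::cor(la, lb),
       per_gene = data.frame(gene = shared, mean_a = mean_a,
                             mean_b = mean_b))
}

#' Anchor iST detection efficiency to a reference assay
#'
#' If the imaging platform detects `fold` times more transcripts per cell
#' than a reference assay of known detection efficiency, the imaging
#' efficiency is `fold * ref_eff`. Given fold-change and reference ranges,
#' returns the implied efficiency interval, clipped at 1. With the
#' published 2.3-2.5x fold over a 14-15% efficient single-nucleus
#' reference this yields roughly 32-38%.
#'
#' @param fold_low,fold_high fold-change range (iST / reference), > 0.
#' @param ref_eff_low,ref_eff_high reference detection efficiency range,
#'   in (0, 1].
#' @return numeric `c(low, high)` efficiency fractions.
#' @export
estimate_detection_efficiency <- function(fold_low, fold_high,
                                          ref_eff_low, ref_eff_high) {
  assert_scalar_number(fold_low, "fold_low", lower = 0, strict_lower = TRUE)
  assert_scalar_number(fold_high, "fold_high", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(ref_eff_low, "ref_eff_low", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(ref_eff_high, "ref_eff_high", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (fold_high < fold_low || ref_eff_high < ref_eff_low) {
    stop_istqc("ranges must satisfy low <= high")
  }
  pmin(c(fold_low * ref_eff_low, fold_high * ref_eff_high), 1)
}

#' Marker co-expression pattern similarity
#'
#' Computes, per matrix, the pairwise Pearson correlations of marker-gene
#' counts across cells (which markers co-occur in the same cells), then
#' compares the two correlation patterns: `r_pattern` is the Pearson
#' correlation between the upper-triangle vectors and `r_squared` its
#' square — the coefficient of determination used to score how faithfully
#' one platform reproduces the co-expression structure seen by another.
#' Markers constant in either matrix are dropped with a warning.
#'
#' @param mA,mB two [cell_by_gene()] matrices.
#' @param markers marker gene ids present in both matrices.
#' @return list with `cor_a`, `cor_b` (marker correlation matrices),
#'   `r_pattern` (signed) and `r_squared`.
#' @export
marker_coexpression_similarity <- function(mA, mB, markers) {
  use <- intersect(intersect(markers, colnames(mA$counts)),
                   colnames(mB$counts))
  ca <- as.matrix(mA$counts[, use, drop = FALSE])
  cb <- as.matrix(mB$counts[, use, drop = FALSE])
  const <- apply(ca, 2L, stats::var) == 0 | apply(cb, 2L, stats::var) == 0
  if (any(const)) {
    warning("dropping constant marker(s): ",
            paste(use[const], collapse = ", "), call. = FALSE)
    use <- use[!const]
    ca <- ca[, use, drop = FALSE]
    cb <- cb[, use, drop = FALSE]
  }
  if (length(use) < 2L) {
    stop_istqc("need at least 2 usable markers with nonzero variance")
  }
  cor_a <- stats::cor(ca)
  cor_b <- stats::cor(cb)
  ut <- upper.tri(cor_a)
  if (sum(ut) < 2L) {
    # 2 markers -> a single pair; pattern correlation needs >= 2 pairs
    stop_istqc("fewer than 2 marker pairs; pattern similarity undefined")
  }
  r <- stats::cor(cor_a[ut], cor_b[ut])
  list(cor_a = cor_a, cor_b = cor_b, r_pattern = r, r_squared = r^2)
}
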