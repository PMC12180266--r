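#' Rank probes by whole-tissue call totals
#'
#' Sums all calls per probe across the tissue (segmentation-free) and
#' flags every target probe whose total falls within the background range,
#' i.e. at or below the highest background-probe total. Such targets
#' cannot be separated from technical noise on counts alone and need the
#' spatial metrics to be rescued. Panel probes with zero calls are kept
#' with total 0. Rows are ordered by descending total; ties break by
#' gene id, so the ranking is stable.
#'
#' @param tt a [transcript_table()].
#' @param panel a [probe_panel()] with at least one background probe.
#' @return A `specificity_table` data.frame: `gene_id`, `kind`,
#'   `total_count`, `rank`, `within_background_range`.
#' @export
probe_count_ranking <- function(tt, panel) {
  if (!any(panel$kind == "background")) {
    stop_istqc("panel contains no background probes")
  }
  counts <- table(factor(tt$gene, levels = panel$gene_id))
  out <- data.frame(
    gene_id = panel$gene_id,
    kind = panel$kind,
    total_count = as.integer(counts[panel$gene_id]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$total_count, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  bg_max <- max(out$total_count[out$kind == "background"])
  out$within_background_range <- out$kind == "target" &
    out$total_count <= bg_max
  rownames(out) <- NULL
  class(out) <- c("specificity_table", "data.frame")
  out
}

#' Global segmentation-free false discovery rate
#'
#' Estimates the fraction of target-gene calls attributable to technical
#' false positives from the background-probe call rate:
#'
#' `FDR(%) = (background_calls / n_background_probes) *
#'           (n_target_genes / total_target_calls) * 100`
#'
#' i.e. the mean calls per background probe divided by the mean calls per
#' target gene, as a percentage. When background and target probes fire at
#' the same per-probe rate the formula gives 100% by algebra; with no
#' background calls it is 0%. All counts are raw whole-tissue totals —
#' the estimate is independent of segmentation, record order and tiling.
#'
#' @param tt a [transcript_table()].
#' @param panel a [probe_panel()] with at least one background probe.
#' @return An `fdr_result` one-row data.frame with `fdr_percent` and the
#'   four formula components.
#' @export
global_fdr <- function(tt, panel) {
  bg <- background_genes(panel)
  tg <- target_genes(panel)
  if (length(bg) == 0L) stop_istqc("panel contains no background probes")
  bg_calls <- sum(tt$gene %in% bg)
  tg_calls <- sum(tt$gene %in% tg)
  if (tg_calls == 0L) stop_istqc("no target-gene calls; FDR undefined")
  out <- data.frame(
    fdr_percent = (bg_calls / length(bg)) * (length(tg) / tg_calls) * 100,
    background_barcode_calls = bg_calls,
    number_of_background_barcodes = length(bg),
    number_of_target_genes = length(tg),
    total_target_gene_calls = tg_calls
  )
  class(out) <- c("fdr_result", "data.frame")
  out
}

#' Moran's I with inverse-distance weights
#'
#' Global spatial autocorrelation of per-cell counts, with weights
#' `w_ij = 1 / d_ij` (Euclidean distance between cell centroids),
#' `w_ii = 0` and no row standardisation:
#'
#' `I = n / S0 * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#'
#' with `S0 = sum_ij w_ij`. Values near 0 indicate spatial randomness,
#' positive values clustering or gradients, negative values
#' checkerboard-like alternation; the permutation expectation is
#' `-1/(n-1)` and the n = 2 value is exactly -1 for any distinct values.
#'
#' @param values numeric per-cell counts of one probe (n >= 2, nonzero
#'   variance).
#' @param centroids n x 2 matrix of cell centroids in micrometres
#'   (pairwise distinct).
#' @return The raw Moran's I.
#' @export
morans_i <- function(values, centroids) {
  centroids <- as.matrix(centroids)
  n <- length(values)
  if (n < 2L || nrow(centroids) != n) {
    stop_istqc("need n >= 2 values with matching centroids")
  }
  W <- inverse_distance_weights(centroids)
  morans_i_w(values, W)
}

# Weight matrix shared across probes of one dataset; errors name the first
# coincident centroid pair.
inverse_distance_weights <- function(centroids) {
  d <- as.matrix(stats::dist(centroids))
  zero <- which(d == 0 & row(d) < col(d), arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    stop_istqc(sprintf("coincident centroids at rows %d and %d",
                       zero[1, 1], zero[1, 2]))
  }
  W <- 1 / d
  diag(W) <- 0
  W
}

morans_i_w <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop_istqc("values have zero variance; Moran's I undefined")
  n * as.numeric(crossprod(z, W %*% z)) / (sum(W) * denom)
}

#' Min-max scale Moran's I values of one dataset
#'
#' Maps the raw Moran's I of all probes (targets and backgrounds jointly)
#' onto \[0, 1\] via `(I - min) / (max - min)`, so probes of one dataset
#' can be compared on a common axis. Strictly monotone, hence
#' rank-preserving. NA values are carried through.
#'
#' @param raw numeric vector of raw Moran's I values (>= 2 finite values).
#' @return Scaled values in \[0, 1\].
#' @export
scale_morans <- function(raw) {
  fin <- raw[is.finite(raw)]
  if (length(fin) < 2L) stop_istqc("need at least 2 finite Moran's I values")
  lo <- min(fin); hi <- max(fin)
  if (hi == lo) stop_istqc("all Moran's I values equal; scaling undefined")
  (raw - lo) / (hi - lo)
}

#' Median nearest-neighbour distance of one probe's calls
#'
#' For each call, the Euclidean distance to the nearest other call of the
#' same probe; the median of that distribution. Small values reveal
#' (sub)cellular clustering — e.g. a lowly expressed marker concentrated
#' in isolated rare cells — whereas spatially random calls at intensity
#' `lambda` per unit area have median NN distance `sqrt(ln 2 / (pi *
#' lambda))`.
#'
#' @param points n x 2 matrix of call positions in micrometres (n >= 2).
#' @return The median NN distance in micrometres.
#' @export
median_nn_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop_istqc("need at least 2 points")
  stats::median(nn_distances(points))
}

#' Classify probe confidence from spatial metrics
#'
#' Probes are stratified into `n_strata` equal-count strata by their
#' scaled Moran's I; within each stratum the nearest-neighbour distance
#' threshold is the `q` quantile of the background probes' median NN
#' distances (falling back to all probes of the stratum when it contains
#' no background). A target is flagged `low_confidence` only when BOTH
#' hold: its total count lies within the background range AND its median
#' NN distance exceeds the stratum threshold (i.e. its calls are spread
#' out like spatially random noise). Lowly abundant but spatially
#' structured probes — small NN distances — are thereby rescued.
#' Raising `q` never increases the number of flags.
#'
#' @param table a `specificity_table` with columns `gene_id`, `kind`,
#'   `morans_i_scaled`, `median_nn_distance`, `within_background_range`
#'   (as built by [specificity_table()]).
#' @param n_strata number of Moran's I strata.
#' @param q quantile of background NN distances used as threshold.
#' @return The table with `stratum` and `low_confidence` columns added.
#' @export
classify_probe_confidence <- function(table, n_strata = 4L, q = 0.95) {
  need <- c("gene_id", "kind", "morans_i_scaled", "median_nn_distance",
            "within_background_range")
  if (!all(need %in% names(table))) {
    stop_istqc("table lacks columns: ",
               paste(setdiff(need, names(table)), collapse = ", "))
  }
  valid <- is.finite(table$morans_i_scaled) &
    is.finite(table$median_nn_distance)
  if (sum(valid) < n_strata) {
    stop_istqc("fewer valid probes than strata")
  }
  table$stratum <- NA_integer_
  # equal-count strata by scaled Moran's I, ties broken by rank order
  rk <- rank(table$morans_i_scaled[valid], ties.method = "first")
  table$stratum[valid] <- as.integer(
    ceiling(rk / (sum(valid) / n_strata))
  )
  table$stratum[valid] <- pmin(table$stratum[valid], n_strata)
  table$low_confidence <- FALSE
  for (s in seq_len(n_strata)) {
    in_s <- valid & table$stratum == s
    if (!any(in_s)) next
    bg_s <- in_s & table$kind == "background"
    pool <- if (any(bg_s)) table$median_nn_distance[bg_s]
            else table$median_nn_distance[in_s]
    thr <- stats::quantile(pool, q, names = FALSE)
    table$low_confidence[in_s] <- table$kind[in_s] == "target" &
      table$within_background_range[in_s] &
      table$median_nn_distance[in_s] > thr
  }
  table
}

#' Fraction of calls inside segmented nuclei
#'
#' The fraction of calls landing on pixels with label > 0 — a simple check
#' that both target and background signals concentrate where RNA is
#' expected. Reported overall, per probe kind, and optionally per probe.
#'
#' @param tt a [transcript_table()].
#' @param mask a [segmentation_mask()].
#' @param panel optional [probe_panel()] to split by probe kind.
#' @param per_probe also report one fraction per probe.
#' @return list with `overall` (NA for an empty table), `by_kind`
#'   (data.frame) and optionally `per_probe`.
#' @export
nuclear_fraction <- function(tt, mask, panel = NULL, per_probe = FALSE) {
  if (!inherits(mask, "segmentation_mask")) {
    stop_istqc("`mask` must be a segmentation_mask")
  }
  n <- nrow(tt)
  if (n == 0L) {
    return(list(overall = NA_real_,
                by_kind = data.frame(kind = character(),
                                     fraction = numeric())))
  }
  s <- mask$pixel_size
  col <- floor(tt$x / s) + 1L
  row <- floor(tt$y / s) + 1L
  inside <- col >= 1L & col <= ncol(mask$labels) &
    row >= 1L & row <= nrow(mask$labels)
  in_nuc <- rep(FALSE, n)
  in_nuc[inside] <- mask$labels[cbind(row[inside], col[inside])] > 0L
  out <- list(overall = mean(in_nuc))
  if (!is.null(panel)) {
    kind <- panel$kind[match(tt$gene, panel$gene_id)]
    out$by_kind <- data.frame(
      kind = sort(unique(stats::na.omit(kind))),
      fraction = as.numeric(tapply(in_nuc, kind, mean)[
        sort(unique(stats::na.omit(kind)))])
    )
  }
  if (per_probe) {
    fr <- tapply(in_nuc, tt$gene, mean)
    out$per_probe <- data.frame(gene_id = names(fr),
                                fraction = as.numeric(fr))
  }
  out
}

#' Per-plane call counts and z-truncation flag
#'
#' Tabulates detected molecules per optical plane and flags a truncated
#' axial distribution: when the count at either edge plane exceeds
#' `edge_frac` of the modal plane count, molecules above/below the imaged
#' volume were likely missed (as happens when the imaged z range does not
#' cover the section).
#'
#' @param tt a [transcript_table()] whose z is a plane index
#'   (`0 .. planes-1`).
#' @param planes number of recorded planes (>= 1).
#' @param edge_frac flag threshold relative to the modal plane count.
#' @return list with `counts` (length `planes`) and `truncation_flag`.
#' @export
z_histogram <- function(tt, planes, edge_frac = 0.5) {
  if (!is.numeric(planes) || planes < 1L) stop_istqc("`planes` must be >= 1")
  z <- tt$z
  if (any(!is.finite(z)) || any(z != round(z)) ||
      any(z < 0) || any(z > planes - 1)) {
    stop_istqc("z is not a plane index in 0..planes-1; supply plane-indexed data")
  }
  counts <- tabulate(as.integer(z) + 1L, nbins = as.integer(planes))
  modal <- max(counts)
  flag <- modal > 0 &&
    (counts[1L] > edge_frac * modal || counts[planes] > edge_frac * modal)
  list(counts = counts, truncation_flag = flag)
}

#' Full specificity table for one dataset
#'
#' Assembles, per panel probe: the whole-tissue call total and
#' background-range flag ([probe_count_ranking()]); Moran's I of the
#' per-cell counts with inverse-distance weights between cell centroids
#' (raw and min-max scaled over all probes, NA when a probe has constant
#' per-cell counts); the median nearest-neighbour distance between the
#' probe's calls (NA below 2 calls); and the low-confidence
#' classification.
#'
#' @param tt a [transcript_table()].
#' @param panel a [probe_panel()].
#' @param mask a [segmentation_mask()] used to derive per-cell counts for
#'   all probes (background included).
#' @param n_strata,q classification parameters, see
#'   [classify_probe_confidence()].
#' @return A `specificity_table` data.frame with one row per panel probe.
#' @export
specificity_table <- function(tt, panel, mask, n_strata = 4L, q = 0.95) {
  tab <- probe_count_ranking(tt, panel)
  asg <- assign_transcripts(tt, mask, panel, include_background = TRUE)
  counts <- asg$matrix$counts
  W <- inverse_distance_weights(asg$matrix$centroids)

  tab$morans_i_raw <- vapply(tab$gene_id, function(g) {
    v <- as.numeric(counts[, g])
    if (stats::var(v) == 0) return(NA_real_)
    morans_i_w(v, W)
  }, 0)
  tab$morans_i_scaled <- if (sum(is.finite(tab$morans_i_raw)) >= 2L &&
                             diff(range(tab$morans_i_raw,
                                        na.rm = TRUE)) > 0) {
    scale_morans(tab$morans_i_raw)
  } else {
    rep(NA_real_, nrow(tab))
  }
  tab$median_nn_distance <- vapply(tab$gene_id, function(g) {
    pts <- tt[tt$gene == g, c("x", "y"), drop = FALSE]
    if (nrow(pts) < 2L) return(NA_real_)
    median_nn_distance(pts)
  }, 0)
  classify_probe_confidence(tab, n_strata = n_strata, q = q)
}
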