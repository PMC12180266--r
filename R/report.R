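#' Run configuration
#'
#' A run configuration collects every tunable parameter of the toolkit
#' with its default made explicit, so each report can serialise the exact
#' settings it was produced under. Stored on disk as YAML.
#'
#' @param ... overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    spot_diameter_um = 55,
    bin_side_um = visium_bin_side(55),
    pseudocount = 0.01,
    n_strata = 4L,
    q = 0.95,
    dedup = list(tile_size = NA_real_, window = NA_real_,
                 max_copies = 400L, min_occurrences = 10L, tol = 0.15),
    neighborhood = list(k = 10L, n_perm = 10000L, alpha = 0.05),
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, list(...))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Assemble a cross-platform comparison report
#'
#' Collects precomputed module outputs for one or more datasets into a
#' platform-feature-style summary table (one row per dataset) and a
#' machine-readable long-format metric table (dataset, metric, value).
#' Nothing is recomputed here: every reported number is a module output,
#' and the configuration is serialised alongside for provenance.
#'
#' Recognised per-dataset entries (all optional, at least one required):
#' `sensitivity` (from [per_cell_summary()]), `fdr` (from
#' [global_fdr()]), `specificity` (a classified [specificity_table()]),
#' `resolution` (from [bead_resolution_summary()]), `assignment` (the
#' `stats` of [assign_transcripts()]), `dedup` (from [dedup_stitch()]).
#'
#' @param datasets named list; one entry per dataset, each a list of the
#'   module results above.
#' @param config a [run_config()] serialised with the report.
#' @param out_dir optional directory; when given, writes `summary.tsv`,
#'   `metrics_long.tsv` and `config.yaml`.
#' @return list with `summary` (wide data.frame), `long` (long
#'   data.frame) and `config`.
#' @export
build_report <- function(datasets, config = run_config(), out_dir = NULL) {
  if (length(datasets) == 0L || is.null(names(datasets))) {
    stop_istqc("`datasets` must be a non-empty named list")
  }
  rows <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    if (length(d) == 0L) stop_istqc("dataset '", nm, "' has no results")
    metric <- function(name, value) {
      data.frame(dataset = nm, metric = name,
                 value = as.numeric(value %||% NA_real_))
    }
    out <- list()
    if (!is.null(d$sensitivity)) {
      s <- d$sensitivity
      out <- c(out, list(
        metric("median_transcripts_per_cell", s$median_transcripts),
        metric("se_transcripts_per_cell", s$se_transcripts),
        metric("median_features_per_cell", s$median_features),
        metric("se_features_per_cell", s$se_features)
      ))
    }
    if (!is.null(d$fdr)) {
      out <- c(out, list(metric("fdr_percent", d$fdr$fdr_percent)))
    }
    if (!is.null(d$specificity)) {
      sp <- d$specificity
      out <- c(out, list(
        metric("n_background_range_targets",
               sum(sp$within_background_range)),
        metric("n_low_confidence_targets",
               sum(sp$low_confidence, na.rm = TRUE))
      ))
    }
    if (!is.null(d$resolution)) {
      r <- d$resolution
      out <- c(out, list(
        metric("fwhm_xy_nm", r$fwhm_xy_nm),
        metric("mad_xy_nm", r$mad_xy_nm)
      ))
    }
    if (!is.null(d$assignment)) {
      out <- c(out, list(
        metric("assigned_fraction", d$assignment$assigned_fraction)
      ))
    }
    if (!is.null(d$dedup)) {
      out <- c(out, list(
        metric("duplicate_rate", d$dedup$duplicate_rate)
      ))
    }
    if (length(out) == 0L) {
      stop_istqc("dataset '", nm, "' contributed no recognised results")
    }
    do.call(rbind, out)
  })
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  summary <- report_summary_from_long(long)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t")
    data.table::fwrite(long, file.path(out_dir, "metrics_long.tsv"),
                       sep = "\t")
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  list(summary = summary, long = long, config = config)
}

#' Rebuild the wide summary from the long-format metric table
#'
#' @param long data.frame with columns `dataset`, `metric`, `value`.
#' @return Wide data.frame, one row per dataset; metrics missing for a
#'   dataset are NA.
#' @export
report_summary_from_long <- function(long) {
  metrics <- unique(long$metric)
  ds <- unique(long$dataset)
  wide <- data.frame(dataset = ds, stringsAsFactors = FALSE)
  for (m in metrics) {
    v <- rep(NA_real_, length(ds))
    sub <- long[long$metric == m, , drop = FALSE]
    v[match(sub$dataset, ds)] <- sub$value
    wide[[m]] <- v
  }
  wide
}
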