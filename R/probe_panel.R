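#' Probe panels
#'
#' A probe panel registers every probe of an iST run as either a `target`
#' (a real gene) or a `background` control. Background probes have no
#' complementary sequence in the sample; the vendors ship them under
#' different names — false-positive probes (Molecular Cartography), blank
#' barcodes (Merscope) or unassigned codewords (Xenium) — captured here as
#' the `background_class`. Their call counts estimate the false-discovery
#' floor of a run and drive the whole specificity module.
#'
#' @param gene_id character probe/gene identifiers (unique).
#' @param kind `"target"` or `"background"` per probe.
#' @param background_class for background probes, one of `"false_positive"`,
#'   `"blank"`, `"unassigned_codeword"`; `"none"` for targets.
#' @return A `probe_panel` data.frame.
#' @export
probe_panel <- function(gene_id, kind,
                        background_class = NULL) {
  gene_id <- as.character(gene_id)
  kind <- match.arg(as.character(kind),
                    c("target", "background"), several.ok = TRUE)
  kind <- rep(kind, length.out = length(gene_id))
  if (anyDuplicated(gene_id)) stop_istqc("panel gene_ids must be unique")
  if (!any(kind == "target")) {
    stop_istqc("panel needs at least one target probe")
  }
  if (is.null(background_class)) {
    background_class <- ifelse(kind == "background", "blank", "none")
  }
  background_class <- rep(as.character(background_class),
                          length.out = length(gene_id))
  ok_bg <- c("false_positive", "blank", "unassigned_codeword")
  bad <- kind == "background" & !background_class %in% ok_bg
  if (any(bad)) {
    stop_istqc("background probes must carry a background_class (",
               paste(ok_bg, collapse = ", "), ")")
  }
  background_class[kind == "target"] <- "none"
  out <- data.frame(gene_id = gene_id, kind = kind,
                    background_class = background_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_panel", "data.frame")
  out
}

#' Read / write a probe panel
#'
#' The on-disk format is a two-column delimited file with columns
#' `gene_id` and `kind`, where `kind` is `target` or
#' `background:<background_class>`.
#'
#' @param path file path.
#' @return [read_probe_panel()] returns a [probe_panel()];
#'   [write_probe_panel()] returns `path` invisibly.
#' @export
read_probe_panel <- function(path) {
  df <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  if (!all(c("gene_id", "kind") %in% names(df))) {
    stop_istqc("panel file needs columns gene_id and kind")
  }
  parts <- strsplit(as.character(df$kind), ":", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1L)
  bgc <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  bgc[kind == "background" & bgc == ""] <- "blank"
  bgc[kind == "target"] <- "none"
  probe_panel(df$gene_id, kind, bgc)
}

#' @rdname read_probe_panel
#' @param panel a [probe_panel()].
#' @export
write_probe_panel <- function(panel, path) {
  kind <- ifelse(panel$kind == "background",
                 paste0("background:", panel$background_class),
                 "target")
  data.table::fwrite(
    data.frame(gene_id = panel$gene_id, kind = kind), path
  )
  invisible(path)
}

target_genes <- function(panel) panel$gene_id[panel$kind == "target"]
background_genes <- function(panel) panel$gene_id[panel$kind == "background"]
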