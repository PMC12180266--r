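#' Transcript tables
#'
#' A transcript table holds one record per detected molecule: the gene (or
#' probe) identity and its spatial position in micrometres. It is the common
#' currency of all iST platforms compared by this package: Molecular
#' Cartography, Merscope and Xenium all emit such a table after on-instrument
#' decoding, differing only in column naming and coordinate units (a
#' "dialect", see [transcript_dialects()]).
#'
#' Coordinates follow the image convention: origin at the top-left of the
#' imaged area, x increasing rightward and y downward, both in micrometres.
#' `z` is either a micrometre position or an integer optical-plane index,
#' depending on the platform; `tile_id` is an optional acquisition-tile
#' label. `record_id` is a unique integer per molecule, assigned
#' sequentially from 0 at load time and preserved by [crop_region()] so that
#' records remain traceable through filtering.
#'
#' @param gene character vector of gene/probe identifiers.
#' @param x,y,z numeric coordinates (micrometres; `z` may be a plane index).
#' @param tile_id optional integer tile label per record.
#' @param record_id optional unique integer ids; defaults to `0:(n-1)`.
#' @param panel optional [probe_panel()] attached for gene-id validation.
#' @return A `transcript_table`, a `data.frame` with columns `gene`, `x`,
#'   `y`, `z`, `tile_id`, `record_id` and attribute `z_mode` (`"um"` or
#'   `"plane"`).
#' @export
transcript_table <- function(gene = character(), x = numeric(),
                             y = numeric(), z = numeric(),
                             tile_id = NULL, record_id = NULL,
                             panel = NULL) {
  n <- length(gene)
  recycle <- function(v) if (length(v) == 1L && n > 1L) rep(v, n) else v
  x <- recycle(x); y <- recycle(y); z <- recycle(z)
  if (length(x) != n || length(y) != n) {
    stop_istqc("`gene`, `x` and `y` must have equal length")
  }
  if (length(z) == 0L && n > 0L) z <- rep(NA_real_, n)
  if (is.null(tile_id)) tile_id <- rep(NA_integer_, n)
  if (is.null(record_id)) record_id <- seq_len(n) - 1L
  tt <- data.frame(
    gene = as.character(gene),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    tile_id = as.integer(tile_id), record_id = as.integer(record_id),
    stringsAsFactors = FALSE
  )
  validate_transcript_table(tt, panel = panel)
  class(tt) <- c("transcript_table", "data.frame")
  attr(tt, "z_mode") <- attr(gene, "z_mode") %||% "um"
  tt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_transcript_table <- function(tt, panel = NULL) {
  if (nrow(tt) > 0L) {
    bad <- which(!is.finite(tt$x) | !is.finite(tt$y))
    if (length(bad) > 0L) {
      stop_istqc("non-finite x/y coordinate at row ", bad[1L])
    }
    if (anyDuplicated(tt$record_id)) {
      stop_istqc("record_id values must be unique")
    }
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(tt$gene), panel$gene_id)
    if (length(unknown) > 0L) {
      stop_istqc(
        "gene ids not in the attached probe panel: ",
        paste(head(unknown, 5L), collapse = ", ")
      )
    }
  }
  invisible(tt)
}

#' Platform dialects for transcript tables
#'
#' Declarative column maps for reading per-molecule transcript tables
#' written by different platforms. Each dialect names the source columns
#' for gene, x, y, z and (optionally) tile id, the coordinate unit
#' (`"um"` or `"px"`), and whether z is a micrometre position or an
#' optical-plane index. Unknown extra columns in a file are ignored.
#'
#' * `generic`: columns `gene, x, y, z, tile_id`, micrometres. This is the
#'   package's own canonical format and the one [write_transcripts()] emits.
#' * `mc`: Molecular Cartography style `x, y, z, gene` with pixel
#'   coordinates (`pixel_size` is required at load time) and z as plane.
#' * `merscope`: `gene, global_x, global_y, global_z` in micrometres with z
#'   as plane index (the instrument images a fixed set of planes).
#' * `xenium`: `feature_name, x_location, y_location, z_location` in
#'   micrometres.
#'
#' @return Named list of dialect descriptors.
#' @export
transcript_dialects <- function() {
  list(
    generic = list(
      cols = c(gene = "gene", x = "x", y = "y", z = "z", tile_id = "tile_id"),
      unit = "um", z_mode = "um"
    ),
    mc = list(
      cols = c(gene = "gene", x = "x", y = "y", z = "z"),
      unit = "px", z_mode = "plane"
    ),
    merscope = list(
      cols = c(gene = "gene", x = "global_x", y = "global_y",
               z = "global_z"),
      unit = "um", z_mode = "plane"
    ),
    xenium = list(
      cols = c(gene = "feature_name", x = "x_location", y = "y_location",
               z = "z_location"),
      unit = "um", z_mode = "um"
    )
  )
}

#' Read a transcript table
#'
#' Reads a per-molecule table in delimited text (CSV/TSV) or Parquet form,
#' mapping platform-specific columns onto the shared data model and
#' converting pixel coordinates to micrometres where the dialect requires
#' it. Row order is preserved and `record_id` is assigned sequentially
#' from 0.
#'
#' @param path file to read (`.parquet` is read via the arrow package,
#'   anything else via [data.table::fread()]).
#' @param dialect name of a dialect from [transcript_dialects()].
#' @param pixel_size micrometres per pixel; required for dialects whose
#'   coordinates are stored in pixels (e.g. `"mc"`).
#' @param panel optional [probe_panel()] used to validate gene ids.
#' @return A [transcript_table()].
#' @export
load_transcripts <- function(path, dialect = "generic", pixel_size = NULL,
                             panel = NULL) {
  if (!file.exists(path)) stop_istqc("file not found: ", path)
  dialects <- transcript_dialects()
  if (!dialect %in% names(dialects)) {
    stop_istqc("unknown dialect '", dialect, "'; known: ",
               paste(names(dialects), collapse = ", "))
  }
  dd <- dialects[[dialect]]
  if (identical(dd$unit, "px")) {
    if (is.null(pixel_size)) {
      stop_istqc("dialect '", dialect,
                 "' stores pixel coordinates; supply `pixel_size`")
    }
    assert_scalar_number(pixel_size, "pixel_size", lower = 0,
                         strict_lower = TRUE)
  }
  raw <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_istqc("reading Parquet requires the arrow package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    as.data.frame(data.table::fread(path, showProgress = FALSE))
  }
  mandatory <- dd$cols[intersect(c("gene", "x", "y"), names(dd$cols))]
  missing_cols <- setdiff(unname(mandatory), names(raw))
  if (length(missing_cols) > 0L) {
    stop_istqc("missing mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  pick <- function(field, default) {
    src <- unname(dd$cols[field])
    if (is.na(src) || !src %in% names(raw)) rep(default, n) else raw[[src]]
  }
  num <- function(v, field) {
    if (is.numeric(v)) return(as.numeric(v))
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0L) {
      stop_istqc(sprintf("non-numeric %s coordinate at row %d", field,
                         bad[1L]))
    }
    out
  }
  x <- num(pick("x", NA_real_), "x")
  y <- num(pick("y", NA_real_), "y")
  z <- num(pick("z", NA_real_), "z")
  if (identical(dd$unit, "px")) {
    x <- x * pixel_size
    y <- y * pixel_size
  }
  tt <- transcript_table(
    gene = as.character(pick("gene", NA_character_)),
    x = x, y = y, z = z,
    tile_id = pick("tile_id", NA_integer_),
    panel = panel
  )
  attr(tt, "z_mode") <- dd$z_mode
  tt
}

#' Write a transcript table in the generic dialect
#'
#' @param tt a [transcript_table()].
#' @param path output file; `.parquet` is written via arrow, anything else
#'   as delimited text via [data.table::fwrite()].
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(tt, path) {
  df <- as.data.frame(tt)[, c("gene", "x", "y", "z", "tile_id")]
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_istqc("writing Parquet requires the arrow package")
    }
    arrow::write_parquet(df, path)
  } else {
    data.table::fwrite(df, path)
  }
  invisible(path)
}

#' Crop a transcript table to a rectangle
#'
#' Retains records with `xmin <= x < xmax` and `ymin <= y < ymax`
#' (half-open on the upper edges, consistent with the pixel convention).
#' Used to exclude folded or damaged tissue areas before analysis.
#' `record_id`s are preserved, so cropping is idempotent and records stay
#' traceable.
#'
#' @param tt a [transcript_table()].
#' @param rect numeric `c(xmin, ymin, xmax, ymax)` in micrometres.
#' @return The cropped `transcript_table`.
#' @export
crop_region <- function(tt, rect) {
  if (length(rect) != 4L || !is.numeric(rect)) {
    stop_istqc("`rect` must be numeric c(xmin, ymin, xmax, ymax)")
  }
  if (!(rect[1] < rect[3]) || !(rect[2] < rect[4])) {
    stop_istqc("degenerate rectangle: need xmin < xmax and ymin < ymax")
  }
  keep <- tt$x >= rect[1] & tt$x < rect[3] &
    tt$y >= rect[2] & tt$y < rect[4]
  out <- tt[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(tt)
  attr(out, "z_mode") <- attr(tt, "z_mode")
  out
}

#' @export
print.transcript_table <- function(x, ...) {
  cat(sprintf("<transcript_table> %d records, %d genes, z as %s\n",
              nrow(x), length(unique(x$gene)), attr(x, "z_mode") %||% "um"))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
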