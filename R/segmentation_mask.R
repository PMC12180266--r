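#' Segmentation masks
#'
#' A 2-D label image: integer matrix where 0 is background and each
#' positive label is one segmented object (nucleus or expanded cell),
#' plus the physical pixel size. Pixel `(row i, col j)` (1-based) covers
#' the half-open square `[(j-1)*s, j*s) x [(i-1)*s, i*s)` micrometres,
#' `s = pixel_size`, so a point maps to exactly one pixel. Object ids
#' need not be contiguous.
#'
#' @param labels integer matrix of labels (0 = background).
#' @param pixel_size micrometres per pixel (> 0).
#' @return A `segmentation_mask` (list with `labels`, `pixel_size`).
#' @export
segmentation_mask <- function(labels, pixel_size) {
  assert_scalar_number(pixel_size, "pixel_size", lower = 0,
                       strict_lower = TRUE)
  if (!is.matrix(labels)) stop_istqc("`labels` must be a matrix")
  lab <- as.integer(round(labels))
  if (any(lab < 0L, na.rm = TRUE)) stop_istqc("labels must be >= 0")
  m <- matrix(lab, nrow = nrow(labels), ncol = ncol(labels))
  structure(list(labels = m, pixel_size = pixel_size),
            class = "segmentation_mask")
}

#' Read / write a segmentation mask as single-channel TIFF
#'
#' Labels are stored as 16-bit grey values, so object ids must be below
#' 65536. The pixel size is not read from TIFF tags; it is supplied
#' explicitly, mirroring how vendor exports ship it in sidecar metadata.
#'
#' @param path TIFF file.
#' @param pixel_size micrometres per pixel.
#' @return [read_mask()] returns a [segmentation_mask()].
#' @export
read_mask <- function(path, pixel_size) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  segmentation_mask(img, pixel_size)
}

#' @rdname read_mask
#' @param mask a [segmentation_mask()].
#' @export
write_mask <- function(mask, path) {
  if (max(mask$labels) > 65535L) stop_istqc("labels exceed 16-bit range")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Cell-by-gene count matrices
#'
#' Per-cell integer transcript counts with cell centroids (micrometres),
#' areas (square micrometres) and optional cell-type labels. Counts are
#' stored sparsely; columns are restricted to panel target genes unless
#' background columns were explicitly requested at assignment time.
#'
#' @param counts a base or `Matrix` matrix, cells x genes, non-negative
#'   integers; rownames are cell ids, colnames gene ids.
#' @param centroids numeric matrix `n_cells x 2` (x, y in micrometres).
#' @param areas numeric vector of cell areas.
#' @param cell_type optional character labels per cell.
#' @return A `cell_by_gene` object.
#' @export
cell_by_gene <- function(counts, centroids, areas = NULL, cell_type = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop_istqc("counts must be non-negative integers")
  }
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != nrow(counts) || ncol(centroids) != 2L) {
    stop_istqc("`centroids` must be an n_cells x 2 matrix")
  }
  colnames(centroids) <- c("x", "y")
  structure(
    list(counts = counts, centroids = centroids,
         areas = areas %||% rep(NA_real_, nrow(counts)),
         cell_type = cell_type),
    class = "cell_by_gene"
  )
}

#' @export
print.cell_by_gene <- function(x, ...) {
  cat(sprintf("<cell_by_gene> %d cells x %d genes, %d counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Assign transcripts to segmented cells
#'
#' Maps every molecule to the mask pixel containing its (x, y) position;
#' molecules over label 0 or outside the mask extent are unassigned.
#' Counts are accumulated per (cell, gene) for panel target genes;
#' background-probe records are excluded from the matrix unless
#' `include_background = TRUE` (the specificity module needs per-cell
#' background counts). Centroids are the unweighted mean of member pixel
#' centers times the pixel size; areas are pixel counts times the pixel
#' area. Every mask label gets a row, including cells with zero counts.
#'
#' @param tt a [transcript_table()].
#' @param mask a [segmentation_mask()].
#' @param panel a [probe_panel()].
#' @param include_background also keep columns for background probes.
#' @return list with `matrix` (a [cell_by_gene()]) and `stats`, a one-row
#'   data.frame `n_total`, `n_assigned`, `assigned_fraction` (the fraction
#'   of all molecules landing on a labelled pixel).
#' @export
assign_transcripts <- function(tt, mask, panel, include_background = FALSE) {
  if (!inherits(mask, "segmentation_mask")) {
    stop_istqc("`mask` must be a segmentation_mask")
  }
  if (is.null(panel) || !any(panel$kind == "target")) {
    stop_istqc("a probe panel with at least one target is required")
  }
  s <- mask$pixel_size
  lab <- mask$labels
  n_total <- nrow(tt)

  col <- floor(tt$x / s) + 1L   # 1-based pixel column
  row <- floor(tt$y / s) + 1L
  inside <- col >= 1L & col <= ncol(lab) & row >= 1L & row <= nrow(lab)
  cell_of <- rep(0L, n_total)
  if (any(inside)) {
    cell_of[inside] <- lab[cbind(row[inside], col[inside])]
  }
  assigned <- cell_of > 0L
  n_assigned <- sum(assigned)

  cells <- sort(setdiff(unique(as.vector(lab)), 0L))
  genes <- if (include_background) panel$gene_id else target_genes(panel)
  keep <- assigned & tt$gene %in% genes
  i <- match(cell_of[keep], cells)
  j <- match(tt$gene[keep], genes)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = rep(1, sum(keep)),
    dims = c(length(cells), length(genes)),
    dimnames = list(as.character(cells), genes)
  )

  # centroid/area per label from pixel membership
  pos <- which(lab > 0L)
  if (length(pos) > 0L) {
    pr <- ((pos - 1L) %% nrow(lab)) + 1L
    pc <- ((pos - 1L) %/% nrow(lab)) + 1L
    f <- factor(lab[pos], levels = cells)
    cx <- tapply((pc - 0.5) * s, f, mean)
    cy <- tapply((pr - 0.5) * s, f, mean)
    npx <- tabulate(f, nbins = length(cells))
  } else {
    cx <- cy <- numeric(0)
    npx <- integer(0)
  }
  m <- cell_by_gene(counts,
                    centroids = cbind(x = as.numeric(cx), y = as.numeric(cy)),
                    areas = npx * s^2)
  stats <- data.frame(
    n_total = n_total, n_assigned = n_assigned,
    assigned_fraction = if (n_total == 0L) 0 else n_assigned / n_total
  )
  list(matrix = m, stats = stats, cell_of = cell_of)
}

#' Read / write a cell-by-gene matrix in MTX triplet form
#'
#' Writes `matrix.mtx` plus sidecars `genes.tsv` (one gene id per line) and
#' `cells.tsv` (cell id, centroid, area, optional cell type); the standard
#' exchange layout for sparse expression matrices.
#'
#' @param m a [cell_by_gene()].
#' @param dir directory to write into / read from.
#' @return [read_cell_by_gene()] returns a [cell_by_gene()].
#' @export
write_cell_by_gene <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(m$counts), file.path(dir, "genes.tsv"))
  cells <- data.frame(
    cell_id = rownames(m$counts),
    x = m$centroids[, "x"], y = m$centroids[, "y"],
    area = m$areas
  )
  if (!is.null(m$cell_type)) cells$cell_type <- m$cell_type
  data.table::fwrite(cells, file.path(dir, "cells.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_cell_by_gene
#' @export
read_cell_by_gene <- function(dir) {
  counts <- as(as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                  "generalMatrix"), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- as.data.frame(data.table::fread(file.path(dir, "cells.tsv")))
  dimnames(counts) <- list(as.character(cells$cell_id), genes)
  cell_by_gene(counts, centroids = cbind(cells$x, cells$y),
               areas = cells$area,
               cell_type = if ("cell_type" %in% names(cells)) {
                 as.character(cells$cell_type)
               })
}
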