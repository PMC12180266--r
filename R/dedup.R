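#' Remove stitch-border duplicate transcripts
#'
#' Imaging tiles that do not overlap perfectly can record the same molecule
#' twice, once on each side of a tile border, with a small consistent
#' offset. For every tile-grid line (vertical lines `x = k * tile_size`
#' and horizontal lines `y = k * tile_size` interior to the data extent)
#' this routine:
#'
#' 1. collects candidate same-gene pairs that straddle the line, with both
#'    members within `window` of it and an along-line offset no larger
#'    than `window`, from genes with fewer than `max_copies` calls in the
#'    window (crowded genes would produce spurious pairings);
#' 2. estimates a consensus shift as the modal pair offset (offsets binned
#'    at `tol` per axis), using only pairs of genes that occur at least
#'    `min_occurrences` times in the window; the modal bin itself must
#'    also hold at least `min_occurrences` pairs — without that support no
#'    consistent shift exists and the line is left untouched;
#' 3. greedily removes, for every pair whose offset matches the consensus
#'    within `tol` per axis (nearest offsets first, each record used at
#'    most once), the member lying farther from the line.
#'
#' Applied to duplicate-free data the procedure is a no-op, so running it
#' twice equals running it once.
#'
#' @param tt a [transcript_table()].
#' @param tile_size tile pitch in the coordinate units of `tt`
#'   (micrometres).
#' @param window half-width of the border band searched on each side of a
#'   grid line; must be `< tile_size / 2`.
#' @param max_copies genes with at least this many calls inside a window
#'   are excluded from pairing.
#' @param min_occurrences minimum calls a gene must have inside the window
#'   for its pairs to enter the consensus-shift estimate, and the minimum
#'   support of the modal offset bin.
#' @param tol per-axis tolerance when matching offsets to the consensus
#'   (micrometres; about one camera pixel).
#' @return list with `transcripts` (duplicates removed), `duplicate_rate`
#'   (removed / total, exactly) and `removed_record_ids`.
#' @export
dedup_stitch <- function(tt, tile_size, window, max_copies = 400L,
                         min_occurrences = 10L, tol = 0.15) {
  assert_scalar_number(tile_size, "tile_size", lower = 0, strict_lower = TRUE)
  if (!is.numeric(window) || window <= 0 || window >= tile_size / 2) {
    stop_istqc("`window` must satisfy 0 < window < tile_size / 2")
  }
  n_total <- nrow(tt)
  removed <- integer(0)
  if (n_total > 0L) {
    for (axis in c("x", "y")) {
      coord <- tt[[axis]]
      other <- tt[[if (axis == "x") "y" else "x"]]
      rng <- range(coord)
      lines_at <- tile_size * seq_len(max(0L, floor(rng[2] / tile_size)))
      lines_at <- lines_at[lines_at > rng[1] & lines_at < rng[2]]
      for (ln in lines_at) {
        removed <- c(removed, dedup_one_line(
          tt, coord, other, ln, window, max_copies, min_occurrences, tol,
          exclude = removed
        ))
      }
    }
  }
  keep <- !tt$record_id %in% removed
  out <- tt[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(tt)
  attr(out, "z_mode") <- attr(tt, "z_mode")
  list(transcripts = out,
       duplicate_rate = if (n_total == 0L) 0 else length(removed) / n_total,
       removed_record_ids = removed)
}

# One grid line: returns record_ids to remove. `coord` is the coordinate
# perpendicular to the line, `other` the coordinate along it.
dedup_one_line <- function(tt, coord, other, ln, window, max_copies,
                           min_occurrences, tol, exclude) {
  inw <- which(abs(coord - ln) <= window & !tt$record_id %in% exclude)
  if (length(inw) < 2L) return(integer(0))
  gene_counts <- table(tt$gene[inw])
  ok_genes <- names(gene_counts)[gene_counts < max_copies]
  inw <- inw[tt$gene[inw] %in% ok_genes]
  left <- inw[coord[inw] < ln]
  right <- inw[coord[inw] >= ln]
  if (length(left) == 0L || length(right) == 0L) return(integer(0))

  # all same-gene left x right combinations with bounded along-line offset
  lg <- split(left, tt$gene[left])
  rg <- split(right, tt$gene[right])
  genes <- intersect(names(lg), names(rg))
  if (length(genes) == 0L) return(integer(0))
  pairs <- do.call(rbind, lapply(genes, function(g) {
    eg <- expand.grid(i = lg[[g]], j = rg[[g]])
    eg$gene <- g
    eg
  }))
  dx <- coord[pairs$j] - coord[pairs$i]
  dy <- other[pairs$j] - other[pairs$i]
  keep <- abs(dy) <= window
  pairs <- pairs[keep, , drop = FALSE]
  dx <- dx[keep]; dy <- dy[keep]
  if (nrow(pairs) == 0L) return(integer(0))

  # consensus shift: modal offset bin over pairs of well-supported genes
  sup_genes <- names(gene_counts)[gene_counts >= min_occurrences]
  sup <- pairs$gene %in% sup_genes
  if (!any(sup)) return(integer(0))
  bin <- paste(round(dx[sup] / tol), round(dy[sup] / tol))
  bin_tab <- table(bin)
  if (max(bin_tab) < min_occurrences) return(integer(0))
  mode_bin <- names(which.max(bin_tab))
  in_mode <- which(sup)[bin == mode_bin]
  cons <- c(mean(dx[in_mode]), mean(dy[in_mode]))

  match_ok <- abs(dx - cons[1]) <= tol & abs(dy - cons[2]) <= tol
  if (!any(match_ok)) return(integer(0))
  cand <- which(match_ok)
  cand <- cand[order(pmax(abs(dx[cand] - cons[1]), abs(dy[cand] - cons[2])))]
  used <- integer(0)
  out <- integer(0)
  for (p in cand) {
    i <- pairs$i[p]; j <- pairs$j[p]
    if (i %in% used || j %in% used) next
    used <- c(used, i, j)
    farther <- if (abs(coord[i] - ln) >= abs(coord[j] - ln)) i else j
    out <- c(out, tt$record_id[farther])
  }
  out
}
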