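#' Spot line profiles
#'
#' A 1-D intensity profile of 21 samples through a called spot (positions
#' -10..10 in x), together with `i_dark`, the darkest pixel intensity of
#' the source image. All optical ratio metrics operate on dark-subtracted
#' intensities `I(x) = raw(x) - i_dark`.
#'
#' @param values numeric vector of exactly 21 raw intensities.
#' @param i_dark darkest pixel of the source image; must not exceed the
#'   profile minimum.
#' @param pixel_size optional pixel size in micrometres.
#' @return A `line_profile` object.
#' @export
line_profile <- function(values, i_dark, pixel_size = NA_real_) {
  if (length(values) != 21L || !is.numeric(values)) {
    stop_istqc("a line profile has exactly 21 intensity samples")
  }
  assert_scalar_number(i_dark, "i_dark")
  if (i_dark > min(values)) {
    stop_istqc("i_dark must be <= the darkest profile sample")
  }
  structure(list(values = as.numeric(values), i_dark = i_dark,
                 pixel_size = pixel_size),
            class = "line_profile")
}

#' Detect local intensity maxima
#'
#' Finds strict local maxima (greater than every neighbour under full
#' 8/26-connectivity) above an intensity threshold in a 2-D or 3-D array,
#' then suppresses peaks closer than `min_distance` pixels to a brighter
#' kept peak. Ties in brightness are broken by lexicographic coordinate
#' order, so detection is deterministic. This is the simple detector used
#' on synthetic bead stacks; real-image spot calling is out of scope.
#'
#' @param image numeric 2-D or 3-D array.
#' @param threshold minimum peak intensity (peaks must exceed it).
#' @param min_distance minimum Euclidean separation in pixels.
#' @return integer matrix of peak coordinates, one row per peak, columns
#'   matching the array dimensions (1-based indices). Zero rows when no
#'   peak qualifies.
#' @export
detect_local_maxima <- function(image, threshold, min_distance = 1) {
  dims <- dim(image)
  nd <- length(dims)
  if (!nd %in% c(2L, 3L)) stop_istqc("image must be 2-D or 3-D")
  padded <- array(-Inf, dim = dims + 2L)
  core <- lapply(dims, function(d) seq(2L, d + 1L))
  if (nd == 2L) {
    padded[core[[1]], core[[2]]] <- image
  } else {
    padded[core[[1]], core[[2]], core[[3]]] <- image
  }

  offsets <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0L, , drop = FALSE]
  is_max <- array(TRUE, dim = dims)
  for (r in seq_len(nrow(offsets))) {
    idx <- lapply(seq_len(nd), function(k) core[[k]] + offsets[r, k])
    nb <- if (nd == 2L) padded[idx[[1]], idx[[2]]]
          else padded[idx[[1]], idx[[2]], idx[[3]]]
    is_max <- is_max & (image > nb)
  }
  cand <- which(is_max & image > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(matrix(integer(), ncol = nd))
  }
  vals <- image[cand]
  ord <- do.call(order, c(list(-vals), lapply(seq_len(nd),
                                              function(k) cand[, k])))
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  kept <- matrix(numeric(), ncol = nd)
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, ]
    if (nrow(kept) == 0L ||
        min(sqrt(rowSums(sweep(kept, 2L, p)^2))) >= min_distance) {
      keep[r] <- TRUE
      kept <- rbind(kept, p)
    }
  }
  out <- cand[keep, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Full width at half maximum of a 1-D profile
#'
#' The baseline is the smaller of the two profile end samples; the half
#' maximum is halfway between baseline and peak, and the two crossings are
#' located by linear interpolation between samples. Invariant under affine
#' intensity transforms `a * I + b` with `a > 0`.
#'
#' @param profile numeric intensity samples.
#' @param spacing sample spacing in micrometres (or any length unit).
#' @return FWHM in the units of `spacing`.
#' @export
fwhm <- function(profile, spacing = 1) {
  n <- length(profile)
  if (n < 3L) stop_istqc("profile too short for a FWHM")
  peak <- which.max(profile)
  if (profile[1] == max(profile) || profile[n] == max(profile)) {
    stop_istqc("profile has no interior peak (monotone or edge maximum)")
  }
  baseline <- min(profile[1], profile[n])
  height <- profile[peak] - baseline
  if (height <= 0) stop_istqc("flat profile: no peak above baseline")
  half <- baseline + height / 2

  left <- NA_real_
  for (i in seq(peak - 1L, 1L)) {
    if (profile[i] <= half) {
      left <- i + (half - profile[i]) / (profile[i + 1L] - profile[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(peak + 1L, n)) {
    if (profile[i] <= half) {
      right <- i - (half - profile[i]) / (profile[i - 1L] - profile[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop_istqc("half maximum not reached inside the profile (plateau wider than profile)")
  }
  (right - left) * spacing
}

#' Median absolute deviation (raw)
#'
#' `median(|x_i - median(x)|)`, with no consistency constant — the robust
#' spread reported alongside median FWHM values.
#'
#' @param values numeric vector (at least one value).
#' @return The raw MAD.
#' @export
mad_raw <- function(values) {
  if (length(values) < 1L || !is.numeric(values)) {
    stop_istqc("`values` must contain at least one number")
  }
  raw_mad(values)
}

#' Bead-based resolution summary
#'
#' Detects beads as local maxima in a 3-D stack, extracts the 1-D
#' intensity lines through each peak along the x, y and z axes, measures
#' the FWHM of each (converted to nanometres via the voxel size), and
#' summarises as median and raw MAD over beads. In-plane resolution is
#' the median of the pooled x and y widths; axial resolution is reported
#' separately.
#'
#' @param stack a `bead_stack` (list with `data` array (z, y, x) and
#'   `voxel` sizes c(x, y, z) in micrometres), as produced by
#'   [simulate_bead_stack()] or built from a TIFF via [read_bead_stack()].
#' @param threshold peak detection threshold.
#' @param min_distance peak separation in pixels.
#' @return A `resolution_summary`: list with `fwhm_xy_nm`, `mad_xy_nm`,
#'   `fwhm_z_nm`, `mad_z_nm`, `n_beads` and the per-bead table.
#' @export
bead_resolution_summary <- function(stack, threshold, min_distance = 5) {
  img <- stack$data
  voxel <- stack$voxel
  peaks <- detect_local_maxima(img, threshold, min_distance)
  if (nrow(peaks) == 0L) stop_istqc("no beads detected above threshold")
  per_bead <- lapply(seq_len(nrow(peaks)), function(b) {
    iz <- peaks[b, 1]; iy <- peaks[b, 2]; ix <- peaks[b, 3]
    fx <- try(fwhm(img[iz, iy, ], voxel[1]), silent = TRUE)
    fy <- try(fwhm(img[iz, , ix], voxel[2]), silent = TRUE)
    fz <- try(fwhm(img[, iy, ix], voxel[3]), silent = TRUE)
    ok <- !inherits(fx, "try-error") && !inherits(fy, "try-error") &&
      !inherits(fz, "try-error")
    if (!ok) return(NULL)
    data.frame(z = iz, y = iy, x = ix,
               fwhm_x_nm = 1000 * fx, fwhm_y_nm = 1000 * fy,
               fwhm_z_nm = 1000 * fz)
  })
  per_bead <- do.call(rbind, per_bead)
  if (is.null(per_bead) || nrow(per_bead) == 0L) {
    stop_istqc("no bead yielded a measurable FWHM on all three axes")
  }
  xy <- c(per_bead$fwhm_x_nm, per_bead$fwhm_y_nm)
  structure(list(
    fwhm_xy_nm = stats::median(xy), mad_xy_nm = raw_mad(xy),
    fwhm_z_nm = stats::median(per_bead$fwhm_z_nm),
    mad_z_nm = raw_mad(per_bead$fwhm_z_nm),
    n_beads = nrow(per_bead), per_bead = per_bead
  ), class = "resolution_summary")
}

#' @export
print.resolution_summary <- function(x, ...) {
  cat(sprintf(
    "<resolution_summary> in-plane FWHM %.0f +/- %.0f nm, axial %.0f +/- %.0f nm (%d beads)\n",
    x$fwhm_xy_nm, x$mad_xy_nm, x$fwhm_z_nm, x$mad_z_nm, x$n_beads
  ))
  invisible(x)
}

#' Read a bead stack from a multi-page TIFF
#'
#' @param path TIFF with one page per z plane.
#' @param voxel voxel sizes `c(x, y, z)` in micrometres.
#' @return A `bead_stack`.
#' @export
read_bead_stack <- function(path, voxel) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  img <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) img[k, , ] <- pages[[k]]
  structure(list(data = img, voxel = voxel), class = "bead_stack")
}

profile_background <- function(p) {
  pos <- -10:10
  v <- p$values - p$i_dark
  v[abs(pos) > 5]
}

#' Signal-to-noise ratio of a spot profile
#'
#' On dark-subtracted intensities, `SNR = (I(0) - mu_bg) / sigma_bg` where
#' the background is the ten outermost samples (`|x| > 5`) of the 21-sample
#' profile and `sigma_bg` is their sample standard deviation.
#'
#' @param p a [line_profile()].
#' @return The SNR.
#' @export
snr <- function(p) {
  bg <- profile_background(p)
  s <- stats::sd(bg)
  if (s == 0) stop_istqc("constant background: sigma_bg = 0")
  v <- p$values - p$i_dark
  (v[11L] - mean(bg)) / s
}

#' Signal-to-background ratio of a spot profile
#'
#' `SBR = I(0) / mu_bg` on dark-subtracted intensities.
#'
#' @param p a [line_profile()].
#' @return The SBR.
#' @export
sbr <- function(p) {
  bg <- profile_background(p)
  mu <- mean(bg)
  if (mu <= 0) stop_istqc("non-positive background mean after dark subtraction")
  v <- p$values - p$i_dark
  v[11L] / mu
}
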