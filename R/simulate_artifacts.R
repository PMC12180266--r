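#' Plant stitch-border duplicate transcripts
#'
#' Emulates the stitching artifact where a molecule near a tile border is
#' recorded in two adjacent tiles with a small consistent offset. Selects
#' the `round(rate * n)` records closest to vertical tile-grid lines
#' (x = k * tile_size, interior to the data extent), and appends for each a
#' copy displaced by `shift = c(dx, dy)` with the dx sign oriented so the
#' copy lands on the other side of the line. Selected records must lie
#' closer to their line than `|dx|`, otherwise the copy could not cross and
#' the pair would not be a border duplicate.
#'
#' @param tt a [transcript_table()].
#' @param rate fraction of records to duplicate, in `[0, 1)`.
#' @param shift numeric `c(dx, dy)` offset in micrometres; `dx > 0`;
#'   for pairs to be recoverable keep `|shift|` inside the dedup window.
#' @param tile_size tile pitch in micrometres.
#' @return list with `transcripts` (input plus appended copies, new
#'   `record_id`s continuing the sequence) and `truth`, a data.frame of
#'   planted pairs (`orig_record_id`, `dup_record_id`, `line_x`).
#' @export
plant_stitch_duplicates <- function(tt, rate, shift, tile_size) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop_istqc("`rate` must be in [0, 1)")
  }
  if (length(shift) != 2L || shift[1] <= 0) {
    stop_istqc("`shift` must be c(dx, dy) with dx > 0")
  }
  n_dup <- round(rate * nrow(tt))
  empty <- data.frame(orig_record_id = integer(), dup_record_id = integer(),
                      line_x = numeric())
  if (n_dup == 0L) return(list(transcripts = tt, truth = empty))

  xr <- range(tt$x)
  lines_x <- tile_size * seq_len(floor(xr[2] / tile_size))
  lines_x <- lines_x[lines_x > xr[1] & lines_x < xr[2]]
  if (length(lines_x) == 0L) {
    stop_istqc("no interior vertical tile-grid line within the data extent")
  }
  near_line <- lines_x[max.col(-abs(outer(tt$x, lines_x, "-")))]
  dist <- abs(tt$x - near_line)
  eligible <- which(dist < shift[1])
  if (length(eligible) < n_dup) {
    stop_istqc("not enough records within |dx| of a grid line to plant ",
               n_dup, " duplicates")
  }
  sel <- eligible[order(dist[eligible], seq_along(eligible))][seq_len(n_dup)]

  sgn <- ifelse(tt$x[sel] < near_line[sel], 1, -1)
  dup <- data.frame(
    gene = tt$gene[sel],
    x = tt$x[sel] + sgn * shift[1],
    y = tt$y[sel] + sgn * shift[2],
    z = tt$z[sel],
    tile_id = tt$tile_id[sel],
    record_id = max(tt$record_id) + seq_len(n_dup)
  )
  out <- rbind(as.data.frame(tt), dup)
  rownames(out) <- NULL
  class(out) <- class(tt)
  attr(out, "z_mode") <- attr(tt, "z_mode")
  truth <- data.frame(orig_record_id = tt$record_id[sel],
                      dup_record_id = dup$record_id,
                      line_x = near_line[sel])
  list(transcripts = out, truth = truth)
}

#' Simulate a 3-D bead image stack with known FWHM
#'
#' Renders sub-resolution fluorescent beads as 3-D Gaussian intensity
#' profiles (isotropic in-plane) of known full width at half maximum at
#' random non-overlapping integer voxel positions, over a constant offset
#' plus Gaussian read noise. The ground-truth FWHM and centers let the
#' bead-resolution pipeline be validated end to end.
#'
#' @param fwhm_xyz true FWHM per axis `c(x, y, z)` in micrometres.
#' @param voxel voxel size `c(x, y, z)` in micrometres.
#' @param n_beads number of beads.
#' @param dim_zyx stack dimensions `c(nz, ny, nx)`.
#' @param amplitude peak amplitude above the offset.
#' @param offset constant intensity offset.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed.
#' @return list with `stack` (a `bead_stack`: intensity array (z, y, x)
#'   plus `voxel`) and `truth` (bead centers in voxel indices, true FWHM).
#' @export
simulate_bead_stack <- function(fwhm_xyz = c(0.47, 0.47, 1.2),
                                voxel = c(0.108, 0.108, 0.3),
                                n_beads = 15L,
                                dim_zyx = c(32L, 160L, 160L),
                                amplitude = 1000,
                                offset = 100,
                                noise_sd = 0,
                                seed = 1L) {
  if (any(fwhm_xyz <= 0) || any(voxel <= 0)) {
    stop_istqc("FWHM and voxel sizes must be positive")
  }
  sigma_px <- (fwhm_xyz / (2 * sqrt(2 * log(2)))) / voxel  # x, y, z
  nz <- dim_zyx[1]; ny <- dim_zyx[2]; nx <- dim_zyx[3]
  margin <- ceiling(4 * sigma_px) + 2L  # x, y, z margins
  min_sep <- max(8 * sigma_px)

  centers <- with_seed(seed, {
    acc <- matrix(NA_real_, 0L, 3L)  # columns x, y, z (voxel index)
    tries <- 0L
    while (nrow(acc) < n_beads && tries < 300L * max(n_beads, 1L)) {
      tries <- tries + 1L
      p <- c(sample(seq(margin[1] + 1L, nx - margin[1]), 1L),
             sample(seq(margin[2] + 1L, ny - margin[2]), 1L),
             sample(seq(margin[3] + 1L, nz - margin[3]), 1L))
      if (nrow(acc) == 0L ||
          min(sqrt(rowSums(sweep(acc, 2L, p)^2))) >= min_sep) {
        acc <- rbind(acc, p)
      }
    }
    if (nrow(acc) < n_beads) {
      stop_istqc("could not place ", n_beads, " beads without overlap")
    }
    acc
  })

  img <- array(offset, dim = c(nz, ny, nx))
  if (n_beads > 0L) {
    for (b in seq_len(n_beads)) {
      cx <- centers[b, 1]; cy <- centers[b, 2]; cz <- centers[b, 3]
      xs <- max(1L, floor(cx - 4 * sigma_px[1])):min(nx, ceiling(cx + 4 * sigma_px[1]))
      ys <- max(1L, floor(cy - 4 * sigma_px[2])):min(ny, ceiling(cy + 4 * sigma_px[2]))
      zs <- max(1L, floor(cz - 4 * sigma_px[3])):min(nz, ceiling(cz + 4 * sigma_px[3]))
      gx <- exp(-(xs - cx)^2 / (2 * sigma_px[1]^2))
      gy <- exp(-(ys - cy)^2 / (2 * sigma_px[2]^2))
      gz <- exp(-(zs - cz)^2 / (2 * sigma_px[3]^2))
      bead <- amplitude * outer(outer(gz, gy), gx)  # (z, y, x)
      img[zs, ys, xs] <- img[zs, ys, xs] + bead
    }
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed + 1L, {
      array(rnorm(length(img), 0, noise_sd), dim = dim(img))
    })
    img[img < 0] <- 0
  }
  stack <- structure(list(data = img, voxel = voxel),
                     class = "bead_stack")
  truth <- list(centers_xyz = centers, fwhm_xyz = fwhm_xyz,
                amplitude = amplitude, offset = offset)
  list(stack = stack, truth = truth)
}

#' Simulate spot line profiles with known SNR and SBR
#'
#' Each profile has 21 samples (positions -10..10 in x around a spot
#' center). The ten outermost samples (`|x| > 5`) form the background
#' annulus used by the estimators; they are drawn as Gaussian noise and
#' affinely standardised to the exact background mean and standard
#' deviation implied by the requested ratios, and the central peak is
#' sized as `mu_bg + snr_true * sigma_bg` (equivalently
#' `sbr_true * mu_bg`). The generator therefore realises the requested
#' SNR and SBR exactly on every profile after dark subtraction — the
#' estimators are validated against construction, not against sampling
#' luck. The required background spread is
#' `sigma_bg = mu_bg * (sbr_true - 1) / snr_true`; parameter combinations
#' driving it to zero or below (the noiseless limit `sbr_true <= 1`) are
#' rejected as degenerate.
#'
#' @param snr_true requested signal-to-noise ratio (> 0).
#' @param sbr_true requested signal-to-background ratio (> 1).
#' @param n number of profiles.
#' @param mu_bg background mean after dark subtraction.
#' @param i_dark darkest-pixel intensity added to all raw samples.
#' @param seed RNG seed.
#' @return list with `profiles` (list of [line_profile()]) and `truth`.
#' @export
simulate_spot_profiles <- function(snr_true, sbr_true, n = 200L,
                                   mu_bg = 50, i_dark = 5, seed = 1L) {
  assert_scalar_number(snr_true, "snr_true", lower = 0, strict_lower = TRUE)
  if (!is.numeric(sbr_true) || length(sbr_true) != 1L || sbr_true <= 1) {
    stop_istqc("degenerate parameters: need sbr_true > 1 (else sigma_bg <= 0)")
  }
  sigma_bg <- mu_bg * (sbr_true - 1) / snr_true
  pos <- -10:10
  bg_idx <- which(abs(pos) > 5)
  profiles <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      v <- numeric(21L)
      raw_bg <- rnorm(length(bg_idx))
      # standardise, then map to the exact requested moments
      raw_bg <- (raw_bg - mean(raw_bg)) / stats::sd(raw_bg)
      v[bg_idx] <- mu_bg + sigma_bg * raw_bg
      shoulder <- setdiff(which(abs(pos) <= 5), which(pos == 0))
      v[shoulder] <- pmax(0, rnorm(length(shoulder), mu_bg, sigma_bg))
      v[pos == 0] <- sbr_true * mu_bg
      line_profile(v + i_dark, i_dark = i_dark)
    })
  })
  list(profiles = profiles,
       truth = list(snr = snr_true, sbr = sbr_true, mu_bg = mu_bg,
                    sigma_bg = sigma_bg, i_dark = i_dark))
}
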