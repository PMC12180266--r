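#' Configuration for the synthetic tissue generator
#'
#' The generator emulates the statistical structure of a medulloblastoma
#' with extensive nodularity (MBEN): a tissue segregated into a *nodular*
#' compartment (postmitotic, neuronally differentiated tumor cells plus
#' astrocyte-like cells) embedded as discs inside an *internodular*
#' compartment (proliferating granule-neuronal-precursor-like cells with
#' stromal and rare immune cells). Each compartment carries cell types with
#' marker-gene expression; detection is Poisson-thinned by a global
#' per-transcript detection efficiency; background probes fire as a
#' homogeneous spatial Poisson process, the null model for technical false
#' positives.
#'
#' Defaults (chosen once as realistic desk-scale study conditions; see the
#' methods vignette): a 1 mm^2 field, 1500 cells/mm^2 placed by a hard-core
#' process with exclusion distance twice the nucleus radius so rendered
#' nuclei never touch, detection efficiency 0.35 (the anchored estimate for
#' automated iST platforms), two nodules of 220 um radius, a rare immune
#' cell type in 0.8% of internodular cells, and ten background probes.
#'
#' @param field_um field width and height in micrometres.
#' @param cell_density cells per mm^2.
#' @param nodules data.frame with columns `x`, `y`, `r` (micrometres)
#'   defining nodular discs; everything else is internodular.
#' @param cell_types named list; each entry is
#'   `list(compartment, proportion, markers)` where `markers` is a named
#'   numeric vector of mean true copies per cell (lambda_g). Proportions
#'   are per compartment and are renormalised within it.
#' @param baseline_lambda mean true copies per cell for every panel gene a
#'   type does not list as a marker (low cross-expression).
#' @param efficiency per-transcript detection efficiency in \[0, 1\].
#' @param background_rates named numeric vector: mean background-probe
#'   calls per mm^2 per probe.
#' @param uniform_target_rates named numeric vector of target-kind probes
#'   whose calls are uniform over the field (spatially random
#'   pseudo-targets used to probe the specificity classifier).
#' @param nucleus_radius nucleus radius in micrometres.
#' @param transcript_radius radius of the disc around the centroid in which
#'   detected transcripts are placed; defaults to `0.8 * nucleus_radius` so
#'   every transcript rasterises inside its own nucleus label.
#' @param thickness_um section thickness; z positions are uniform in it.
#' @param pixel_size mask pixel size in micrometres.
#' @param seed RNG seed.
#' @return A `tissue_sim_config` list.
#' @export
tissue_sim_config <- function(field_um = c(1000, 1000),
                              cell_density = 1500,
                              nodules = data.frame(
                                x = c(300, 700), y = c(320, 660),
                                r = c(220, 220)
                              ),
                              cell_types = default_cell_types(),
                              baseline_lambda = 0.05,
                              efficiency = 0.35,
                              background_rates = stats::setNames(
                                rep(c(200, 250, 300, 350, 400), each = 2),
                                paste0("BG", 1:10)
                              ),
                              uniform_target_rates = numeric(),
                              nucleus_radius = 4,
                              transcript_radius = NULL,
                              thickness_um = 10,
                              pixel_size = 0.5,
                              seed = 1L) {
  assert_scalar_number(efficiency, "efficiency", 0, 1)
  assert_scalar_number(cell_density, "cell_density", lower = 0)
  assert_scalar_number(nucleus_radius, "nucleus_radius", lower = 0,
                       strict_lower = TRUE)
  if (nrow(nodules) > 0L) {
    inside <- nodules$x - nodules$r >= 0 & nodules$x + nodules$r <= field_um[1] &
      nodules$y - nodules$r >= 0 & nodules$y + nodules$r <= field_um[2]
    if (!all(inside)) stop_istqc("nodules must lie inside the field")
  }
  structure(list(
    field_um = field_um, cell_density = cell_density, nodules = nodules,
    cell_types = cell_types, baseline_lambda = baseline_lambda,
    efficiency = efficiency, background_rates = background_rates,
    uniform_target_rates = uniform_target_rates,
    nucleus_radius = nucleus_radius,
    transcript_radius = transcript_radius %||% (0.8 * nucleus_radius),
    thickness_um = thickness_um, pixel_size = pixel_size,
    seed = as.integer(seed)
  ), class = "tissue_sim_config")
}

#' Default MBEN-like cell type panel
#'
#' Two nodular types (differentiated neuronal-like, astrocyte-like), two
#' internodular types (proliferating CGNP-like, stromal) and a rare immune
#' type (0.8% of internodular cells) marked by CD19 — the constellation
#' that lets a lowly abundant but spatially structured marker be told apart
#' from a spatially random background probe.
#'
#' @return Named list of cell type descriptors for [tissue_sim_config()].
#' @export
default_cell_types <- function() {
  list(
    neuronal_diff = list(
      compartment = "nodular", proportion = 0.7,
      markers = c(NRXN3 = 60, RBFOX3 = 40)
    ),
    astro_like = list(
      compartment = "nodular", proportion = 0.3,
      markers = c(AQP4 = 50, NRXN3 = 10)
    ),
    cgnp_like = list(
      compartment = "internodular", proportion = 0.692,
      markers = c(LAMA2 = 50, GLI1 = 30, PTCH1 = 25, MKI67 = 30)
    ),
    stromal = list(
      compartment = "internodular", proportion = 0.3,
      markers = c(LAMA2 = 20, COL1A1 = 40)
    ),
    immune_rare = list(
      compartment = "internodular", proportion = 0.008,
      markers = c(CD19 = 25)
    )
  )
}

sim_panel_genes <- function(cfg) {
  unique(c(
    unlist(lapply(cfg$cell_types, function(ct) names(ct$markers))),
    names(cfg$uniform_target_rates)
  ))
}

# Hard-core point process: sequential proposals, rejected when closer than
# `rmin` to an accepted point; grid-hashed neighbour lookup.
hardcore_points <- function(n, field, rmin, max_tries_factor = 200L) {
  pts <- matrix(NA_real_, nrow = n, ncol = 2L)
  cell_sz <- max(rmin, 1e-6)
  nx <- max(1L, ceiling(field[1] / cell_sz))
  ny <- max(1L, ceiling(field[2] / cell_sz))
  grid <- vector("list", nx * ny)
  accepted <- 0L
  tries <- 0L
  max_tries <- max_tries_factor * n
  while (accepted < n && tries < max_tries) {
    tries <- tries + 1L
    p <- c(runif(1, 0, field[1]), runif(1, 0, field[2]))
    gx <- min(nx, 1L + floor(p[1] / cell_sz))
    gy <- min(ny, 1L + floor(p[2] / cell_sz))
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      cx <- gx + dx; cy <- gy + dy
      if (cx < 1L || cx > nx || cy < 1L || cy > ny) next
      for (q in grid[[(cy - 1L) * nx + cx]]) {
        if (sum((pts[q, ] - p)^2) < rmin^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      accepted <- accepted + 1L
      pts[accepted, ] <- p
      key <- (gy - 1L) * nx + gx
      grid[[key]] <- c(grid[[key]], accepted)
    }
  }
  if (accepted < n) {
    stop_istqc(sprintf(
      "hard-core packing failed: placed %d of %d cells (density infeasible)",
      accepted, n
    ))
  }
  pts
}

in_nodule <- function(x, y, nodules) {
  if (nrow(nodules) == 0L) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(nrow(nodules))) {
    inside <- inside |
      (x - nodules$x[k])^2 + (y - nodules$y[k])^2 <= nodules$r[k]^2
  }
  inside
}

#' Simulate an MBEN-like tissue with known ground truth
#'
#' Places cells by a hard-core point process, assigns compartments by
#' nodule membership and cell types by per-compartment proportions, draws
#' each cell's detected count for gene g as Poisson(efficiency * lambda_g),
#' scatters those transcripts uniformly in a disc around the nucleus
#' centroid, adds homogeneous-Poisson background-probe calls (uniform in
#' x, y and z — the spatial-randomness null for technical false
#' positives), and renders the nuclei as label discs into a segmentation
#' mask. Deterministic per seed, with independently seeded sub-streams per
#' layer (cells, types, counts, positions, background), so e.g. changing
#' only the efficiency leaves cell positions untouched.
#'
#' @param cfg a [tissue_sim_config()].
#' @return list with `transcripts` ([transcript_table()]), `mask`
#'   ([segmentation_mask()]), `panel` ([probe_panel()]) and `truth` (cells
#'   data.frame, expected detected counts per gene and type, config).
#' @export
simulate_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "tissue_sim_config"))
  seeds <- derive_seeds(cfg$seed, 5L)
  area_mm2 <- prod(cfg$field_um) / 1e6
  n_cells <- round(cfg$cell_density * area_mm2)

  # inset by the nucleus radius so every rendered nucleus lies fully
  # inside the field (border cells would otherwise lose transcripts)
  inset <- cfg$nucleus_radius
  centroids <- with_seed(seeds[1L], {
    hardcore_points(n_cells, cfg$field_um - 2 * inset,
                    2 * cfg$nucleus_radius)
  })
  centroids <- centroids + inset

  compartment <- ifelse(in_nodule(centroids[, 1], centroids[, 2],
                                  cfg$nodules),
                        "nodular", "internodular")
  type_names <- names(cfg$cell_types)
  type <- with_seed(seeds[2L], {
    out <- character(n_cells)
    for (comp in unique(compartment)) {
      idx <- which(compartment == comp)
      tns <- type_names[vapply(cfg$cell_types,
                               function(ct) ct$compartment == comp,
                               logical(1))]
      if (length(tns) == 0L) stop_istqc("no cell type for compartment ", comp)
      pr <- vapply(cfg$cell_types[tns], function(ct) ct$proportion, 0)
      out[idx] <- sample(tns, length(idx), replace = TRUE,
                         prob = pr / sum(pr))
    }
    out
  })

  genes <- sim_panel_genes(cfg)
  # lambda matrix: type x gene, baseline everywhere, markers override
  lam <- matrix(cfg$baseline_lambda, nrow = length(type_names),
                ncol = length(genes),
                dimnames = list(type_names, genes))
  for (tn in type_names) {
    mk <- cfg$cell_types[[tn]]$markers
    lam[tn, names(mk)] <- mk
  }
  if (length(cfg$uniform_target_rates) > 0L) {
    lam[, names(cfg$uniform_target_rates)] <- 0  # uniform, not cellular
  }

  counts <- with_seed(seeds[3L], {
    mu <- cfg$efficiency * lam[type, , drop = FALSE]
    matrix(rpois(length(mu), as.vector(mu)), nrow = n_cells,
           dimnames = list(NULL, genes))
  })

  pos <- with_seed(seeds[4L], {
    tot <- sum(counts)
    cell_idx <- rep(rep(seq_len(n_cells), times = ncol(counts)),
                    times = as.vector(counts))
    gene_idx <- rep(rep(seq_along(genes), each = n_cells),
                    times = as.vector(counts))
    r <- cfg$transcript_radius * sqrt(runif(tot))
    th <- runif(tot, 0, 2 * pi)
    data.frame(
      gene = genes[gene_idx],
      x = centroids[cell_idx, 1] + r * cos(th),
      y = centroids[cell_idx, 2] + r * sin(th),
      z = runif(tot, 0, cfg$thickness_um),
      cell = cell_idx
    )
  })

  bg <- with_seed(seeds[5L], {
    rates <- c(cfg$background_rates, cfg$uniform_target_rates)
    ns <- rpois(length(rates), rates * area_mm2)
    data.frame(
      gene = rep(names(rates), times = ns),
      x = runif(sum(ns), 0, cfg$field_um[1]),
      y = runif(sum(ns), 0, cfg$field_um[2]),
      z = runif(sum(ns), 0, cfg$thickness_um),
      cell = NA_integer_
    )
  })

  all_pts <- rbind(pos, bg)
  tt <- transcript_table(all_pts$gene, all_pts$x, all_pts$y, all_pts$z)

  panel <- probe_panel(
    gene_id = c(genes, names(cfg$background_rates)),
    kind = c(rep("target", length(genes)),
             rep("background", length(cfg$background_rates))),
    background_class = c(rep("none", length(genes)),
                         rep("blank", length(cfg$background_rates)))
  )

  mask <- render_nuclei_mask(centroids, cfg$nucleus_radius, cfg$field_um,
                             cfg$pixel_size)

  truth <- list(
    cells = data.frame(cell = seq_len(n_cells), x = centroids[, 1],
                       y = centroids[, 2], compartment = compartment,
                       type = type),
    expected_counts = cfg$efficiency * lam,
    transcript_cell = all_pts$cell,
    config = cfg
  )
  list(transcripts = tt, mask = mask, panel = panel, truth = truth)
}

# Render non-touching nucleus discs as a label image; a pixel belongs to a
# nucleus when its center lies within `radius` of the centroid.
render_nuclei_mask <- function(centroids, radius, field, pixel_size) {
  nc <- ceiling(field[1] / pixel_size)
  nr <- ceiling(field[2] / pixel_size)
  lab <- matrix(0L, nrow = nr, ncol = nc)
  rpx <- radius / pixel_size
  for (i in seq_len(nrow(centroids))) {
    cx <- centroids[i, 1] / pixel_size  # in pixel units
    cy <- centroids[i, 2] / pixel_size
    jr <- max(1L, floor(cx - rpx)):min(nc, ceiling(cx + rpx) + 1L)
    ir <- max(1L, floor(cy - rpx)):min(nr, ceiling(cy + rpx) + 1L)
    px <- outer(ir - 0.5, jr - 0.5, function(yy, xx) {
      (xx - cx)^2 + (yy - cy)^2 <= rpx^2
    })
    sub <- lab[ir, jr, drop = FALSE]
    sub[px] <- i
    lab[ir, jr] <- sub
  }
  segmentation_mask(lab, pixel_size)
}
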