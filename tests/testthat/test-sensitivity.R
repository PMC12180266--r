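test_that("the Visium-equivalent bin side matches the closed form", {
  expect_equal(round(visium_bin_side(55), 2), 48.74)
  expect_equal(visium_bin_side(0), 0)
  expect_equal(round(visium_bin_side(100), 2), 88.62)
  # area equivalence to machine precision
  expect_equal(visium_bin_side(55)^2, pi * (55 / 2)^2, tolerance = 1e-14)
  expect_error(visium_bin_side(-1), ">= 0")
})

test_that("bin_counts matches a brute-force point-to-bin assignment", {
  tt <- random_tt(50, n_genes = 5, field = c(30, 30), seed = 21L)
  side <- 7
  grid <- bin_counts(tt, side)
  # oracle
  ox <- min(tt$x); oy <- min(tt$y)
  key <- paste(floor((tt$x - ox) / side), floor((tt$y - oy) / side))
  oracle <- table(key)
  for (k in names(oracle)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    row <- grid$bins[grid$bins$bin_x == ij[1] & grid$bins$bin_y == ij[2], ]
    expect_equal(row$total, as.integer(oracle[[k]]))
  }
  expect_equal(sum(grid$bins$total), nrow(tt))     # conservation
  # feature counts: genes with > 0 in bin
  expect_true(all(grid$bins$features <= 5))
})

test_that("bin totals are invariant to translation by a grid period", {
  tt <- random_tt(200, field = c(50, 50), seed = 22L)
  side <- 10
  g1 <- bin_counts(tt, side)
  shifted <- transcript_table(tt$gene, tt$x + 3 * side, tt$y + 2 * side,
                              tt$z)
  g2 <- bin_counts(shifted, side)
  expect_equal(g1$bins$total, g2$bins$total)
  expect_equal(g1$bins$features, g2$bins$features)
})

test_that("degenerate binning inputs behave as declared", {
  empty <- bin_counts(transcript_table(), 10)
  expect_equal(nrow(empty$bins), 0L)
  one_bin <- bin_counts(random_tt(20, field = c(5, 5), seed = 1L), 100)
  expect_equal(nrow(one_bin$bins), 1L)
  expect_equal(one_bin$bins$total, 20L)
})

test_that("per-cell medians equal direct order statistics", {
  counts <- Matrix::Matrix(
    matrix(c(3, 0,
             1, 1,
             5, 2,
             0, 0,
             7, 4), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("gA", "gB"))), sparse = TRUE)
  m <- cell_by_gene(counts, centroids = cbind(1:5, 1:5))
  s <- per_cell_summary(m, n_boot = 200, seed = 1L)
  tx <- c(3, 2, 7, 0, 11)
  ft <- c(1, 2, 2, 0, 2)
  expect_equal(s$median_transcripts, sort(tx)[3])
  expect_equal(s$median_features, sort(ft)[3])
  expect_gt(s$se_transcripts, 0)

  single <- cell_by_gene(counts[1, , drop = FALSE],
                         centroids = cbind(1, 1))
  s1 <- per_cell_summary(single)
  expect_equal(s1$median_transcripts, 3)
  expect_equal(s1$median_features, 1)

  absent <- per_cell_summary(m, genes = "gZ")
  expect_equal(absent$median_transcripts, 0)
  expect_equal(absent$median_features, 0)
})

test_that("gene-mean correlation is exact on oracle fixtures", {
  set.seed(31)
  counts_a <- matrix(rpois(200 * 8, lambda = rep(c(2, 5, 10, 20, 1, 8, 15, 3),
                                                 each = 200)),
                     ncol = 8, dimnames = list(NULL, paste0("g", 1:8)))
  mA <- cell_by_gene(Matrix::Matrix(counts_a, sparse = TRUE),
                     centroids = cbind(1:200, 1:200))
  # identical matrices: r = 1
  expect_equal(gene_mean_correlation(mA, mA)$r, 1)
  # doubling: exact affine shift in log space at zero pseudocount
  mB <- cell_by_gene(Matrix::Matrix(2 * counts_a, sparse = TRUE),
                     centroids = cbind(1:200, 1:200))
  expect_equal(gene_mean_correlation(mA, mB, pseudocount = 0)$r, 1,
               tolerance = 1e-12)
  # random fixture equals the textbook formula
  counts_c <- matrix(rpois(200 * 8, 6), ncol = 8,
                     dimnames = list(NULL, paste0("g", 1:8)))
  mC <- cell_by_gene(Matrix::Matrix(counts_c, sparse = TRUE),
                     centroids = cbind(1:200, 1:200))
  got <- gene_mean_correlation(mA, mC)
  expect_equal(got$r, pearson_oracle(log10(colMeans(counts_a) + 0.01),
                                     log10(colMeans(counts_c) + 0.01)))
  expect_equal(got$per_gene$mean_a, unname(colMeans(counts_a)))
  # contract: too few genes
  tiny <- cell_by_gene(Matrix::Matrix(counts_a[, 1:2], sparse = TRUE),
                       centroids = cbind(1:200, 1:200))
  expect_error(gene_mean_correlation(tiny, tiny), "3 shared genes")
})

test_that("detection-efficiency anchoring multiplies fold by reference", {
  expect_equal(estimate_detection_efficiency(2.3, 2.5, 0.14, 0.15),
               c(0.322, 0.375))
  expect_equal(estimate_detection_efficiency(1, 1, 0.2, 0.2), c(0.2, 0.2))
  expect_equal(estimate_detection_efficiency(2, 2, 0.15, 0.15), c(0.3, 0.3))
  expect_equal(estimate_detection_efficiency(10, 10, 0.5, 0.5), c(1, 1))
  expect_error(estimate_detection_efficiency(2.5, 2.3, 0.14, 0.15), "low <= high")
  expect_error(estimate_detection_efficiency(-1, 2, 0.1, 0.2))
})

test_that("marker co-expression similarity equals the triangle-vector oracle", {
  set.seed(41)
  n <- 300
  base <- rpois(n, 5)
  counts_a <- cbind(m1 = base + rpois(n, 2),
                    m2 = base + rpois(n, 2),
                    m3 = rpois(n, 5),
                    m4 = rpois(n, 3))
  mA <- cell_by_gene(Matrix::Matrix(counts_a, sparse = TRUE),
                     centroids = cbind(seq_len(n), seq_len(n)))
  expect_equal(marker_coexpression_similarity(mA, mA,
                                              colnames(counts_a))$r_squared,
               1)
  # partially anti-patterned: reflect one marker column
  counts_b <- counts_a
  counts_b[, "m2"] <- max(counts_b[, "m2"]) - counts_b[, "m2"]
  mB <- cell_by_gene(Matrix::Matrix(counts_b, sparse = TRUE),
                     centroids = cbind(seq_len(n), seq_len(n)))
  got <- marker_coexpression_similarity(mA, mB, colnames(counts_a))
  ca <- cor(counts_a); cb <- cor(counts_b)
  oracle_r <- pearson_oracle(ca[upper.tri(ca)], cb[upper.tri(cb)])
  expect_equal(got$r_pattern, oracle_r)
  expect_equal(got$r_squared, oracle_r^2)
  expect_lt(got$r_pattern, 0)

  # constant marker dropped with a warning; too few pairs is an error
  counts_c <- counts_a
  counts_c[, "m4"] <- 7
  mC <- cell_by_gene(Matrix::Matrix(counts_c, sparse = TRUE),
                     centroids = cbind(seq_len(n), seq_len(n)))
  expect_warning(marker_coexpression_similarity(mA, mC, colnames(counts_a)),
                 "constant")
  expect_error(
    suppressWarnings(marker_coexpression_similarity(mA, mC, c("m1", "m4"))),
    "markers"
  )
})

test_that("simulated tissues recover truth-level sensitivity", {
  cfg <- function(eff, seed) tissue_sim_config(
    cell_density = 500, efficiency = eff, seed = seed,
    nodules = data.frame(x = 500, y = 500, r = 300)
  )
  lo <- simulate_tissue(cfg(0.2, 13L))
  hi <- simulate_tissue(cfg(0.4, 13L))
  asg_lo <- assign_transcripts(lo$transcripts, lo$mask, lo$panel)
  asg_hi <- assign_transcripts(hi$transcripts, hi$mask, hi$panel)
  # per-gene means across the two runs correlate near 1 (only eff differs)
  r <- gene_mean_correlation(asg_lo$matrix, asg_hi$matrix)$r
  expect_gt(r, 0.95)
  # per-gene mean within 3 SE of eff * lambda for a nodular marker
  nod_cells <- lo$truth$cells$type == "neuronal_diff"
  n_nod <- sum(nod_cells)
  counts <- tabulate(lo$truth$transcript_cell[lo$transcripts$gene == "NRXN3"],
                     nbins = nrow(lo$truth$cells))
  mu_hat <- mean(counts[nod_cells])
  expect_lt(abs(mu_hat - 0.2 * 60), 3 * sqrt(0.2 * 60 / n_nod))
})
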