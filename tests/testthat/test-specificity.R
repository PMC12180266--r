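# Build a transcript table with an exact number of calls per probe; the
# positions are irrelevant for count-based metrics.
calls_tt <- function(counts) {
  gene <- rep(names(counts), times = counts)
  n <- length(gene)
  transcript_table(gene, x = seq_len(n), y = rep(1, n), z = 0)
}

test_that("probe ranking flags targets inside the background count range", {
  panel <- probe_panel(c("T1", "T2", "T3", "B1", "B2"),
                       c("target", "target", "target",
                         "background", "background"))
  tt <- calls_tt(c(T1 = 40, T2 = 60, T3 = 100, B1 = 50, B2 = 10))
  tab <- probe_count_ranking(tt, panel)
  flag <- setNames(tab$within_background_range, tab$gene_id)
  expect_true(flag[["T1"]])    # 40 <= max(bg) = 50
  expect_false(flag[["T2"]])   # 60 > 50
  expect_false(any(tab$within_background_range[tab$kind == "background"]))

  # complete separation: no flags
  sep <- calls_tt(c(T1 = 90, T2 = 80, T3 = 70, B1 = 5, B2 = 3))
  expect_equal(sum(probe_count_ranking(sep, panel)$within_background_range),
               0L)
  expect_error(
    probe_count_ranking(tt, probe_panel(c("T1", "T2"), c("target", "target"))),
    "background"
  )
})

test_that("probe ranking equals a brute-force stable sort", {
  panel <- probe_panel(paste0("P", 1:8),
                       c(rep("target", 6), "background", "background"))
  cnt <- c(P1 = 12, P2 = 40, P3 = 12, P4 = 7, P5 = 99, P6 = 0,
           P7 = 12, P8 = 3)
  tab <- probe_count_ranking(calls_tt(cnt[cnt > 0]), panel)
  oracle <- names(cnt)[order(-cnt, names(cnt))]
  expect_equal(tab$gene_id, oracle)
  expect_equal(tab$rank, 1:8)
  expect_equal(setNames(tab$total_count, tab$gene_id)[names(cnt)],
               cnt, ignore_attr = TRUE)
})

test_that("the global FDR formula evaluates exactly", {
  panel <- probe_panel(
    c(paste0("T", 1:5), "B1", "B2"),
    c(rep("target", 5), "background", "background")
  )
  counts <- c(T1 = 500, T2 = 300, T3 = 150, T4 = 40, T5 = 10,
              B1 = 6, B2 = 4)
  tt <- calls_tt(counts)
  res <- global_fdr(tt, panel)
  expect_equal(res$fdr_percent, (10 / 2) * (5 / 1000) * 100)  # 2.5
  expect_equal(res$fdr_percent, 2.5)
  # recomputing from the reported components reproduces the value
  expect_equal(
    with(res, (background_barcode_calls / number_of_background_barcodes) *
           (number_of_target_genes / total_target_gene_calls) * 100),
    res$fdr_percent
  )
  # record order is irrelevant
  perm <- tt[sample(nrow(tt)), ]
  class(perm) <- class(tt)
  expect_equal(global_fdr(perm, panel)$fdr_percent, 2.5)

  # zero background calls -> 0%
  none <- calls_tt(counts[1:5])
  expect_equal(global_fdr(none, panel)$fdr_percent, 0)
  # equal per-probe rates -> exactly 100%
  eq <- calls_tt(c(T1 = 7, T2 = 7, T3 = 7, T4 = 7, T5 = 7, B1 = 7, B2 = 7))
  expect_equal(global_fdr(eq, panel)$fdr_percent, 100)
  expect_error(global_fdr(calls_tt(c(B1 = 3)), panel), "target")
})

test_that("Moran's I matches its closed forms and the double-sum oracle", {
  # n = 2: exactly -1 for any distinct values
  expect_equal(morans_i(c(3, 10), cbind(c(0, 5), c(0, 0))), -1)
  expect_equal(morans_i(c(-2, 7), cbind(c(1, 2), c(3, 9))), -1)

  set.seed(51)
  for (n in c(10, 60, 200)) {
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    v <- rpois(n, 3)
    if (var(v) == 0) v[1] <- v[1] + 1
    expect_equal(morans_i(v, pts), moran_oracle(v, pts), tolerance = 1e-10)
  }

  # clustered high values among distant zeros: positive autocorrelation
  pts <- rbind(cbind(runif(10, 0, 2), runif(10, 0, 2)),
               cbind(runif(40, 50, 100), runif(40, 50, 100)))
  v <- c(rpois(10, 20), rep(0, 40))
  expect_gt(morans_i(v, pts), 0)

  expect_error(morans_i(rep(2, 10), cbind(1:10, 1:10)), "variance")
  expect_error(morans_i(c(1, 2, 3), cbind(c(0, 1, 1), c(0, 2, 2))),
               "rows 2 and 3")
})

test_that("the permutation mean of Moran's I is -1/(n-1)", {
  set.seed(52)
  n <- 40
  pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  v <- rpois(n, 4)
  perms <- replicate(200, morans_i(sample(v), pts))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 3 * se)
})

test_that("min-max scaling maps endpoints and preserves order", {
  expect_equal(scale_morans(c(0, 0.5, 1)), c(0, 0.5, 1))
  set.seed(53)
  raw <- rnorm(20)
  sc <- scale_morans(raw)
  expect_equal(sc[which.min(raw)], 0)
  expect_equal(sc[which.max(raw)], 1)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(cor(raw, sc, method = "spearman"), 1)
  expect_error(scale_morans(rep(0.3, 5)), "equal")
})

test_that("median NN distance handles pairs, lattices and Poisson fields", {
  expect_equal(median_nn_distance(cbind(c(0, 3), c(0, 4))), 5)
  g <- as.matrix(expand.grid(x = seq(0, 19) * 2.5, y = seq(0, 19) * 2.5))
  expect_equal(median_nn_distance(g), 2.5)
  expect_error(median_nn_distance(cbind(1, 1)), "2 points")

  # homogeneous Poisson, lambda = 1 / um^2: median = sqrt(ln 2 / pi)
  set.seed(54)
  n <- 5000
  side <- sqrt(n)
  pts <- cbind(runif(n, 0, side), runif(n, 0, side))
  d <- istqc:::nn_distances(pts)
  med <- median(d)
  boot <- replicate(200, median(d[sample.int(n, replace = TRUE)]))
  expect_lt(abs(med - sqrt(log(2) / pi)), 3 * sd(boot))
})

test_that("probe confidence classification matches a per-stratum quantile oracle", {
  set.seed(55)
  n_probe <- 24
  tab <- data.frame(
    gene_id = sprintf("P%02d", 1:n_probe),
    kind = rep(c("target", "background"), each = 12),
    morans_i_scaled = runif(n_probe),
    median_nn_distance = runif(n_probe, 5, 40),
    within_background_range = rep(c(TRUE, FALSE), n_probe / 2)
  )
  got <- classify_probe_confidence(tab, n_strata = 4, q = 0.95)
  # oracle: equal-count strata on rank, background quantile threshold
  rk <- rank(tab$morans_i_scaled, ties.method = "first")
  stratum <- pmin(ceiling(rk / (n_probe / 4)), 4)
  for (i in seq_len(n_probe)) {
    in_s <- stratum == stratum[i]
    bg <- in_s & tab$kind == "background"
    pool <- if (any(bg)) tab$median_nn_distance[bg]
            else tab$median_nn_distance[in_s]
    thr <- quantile(pool, 0.95, names = FALSE)
    expected <- tab$kind[i] == "target" &&
      tab$within_background_range[i] &&
      tab$median_nn_distance[i] > thr
    expect_equal(got$low_confidence[i], expected)
  }
})

test_that("classification respects ties, the count gate and q-monotonicity", {
  tab <- data.frame(
    gene_id = paste0("P", 1:8),
    kind = c(rep("target", 4), rep("background", 4)),
    morans_i_scaled = seq(0, 1, length.out = 8),
    median_nn_distance = rep(10, 8),          # all identical
    within_background_range = rep(TRUE, 8)
  )
  got <- classify_probe_confidence(tab, n_strata = 2, q = 0.95)
  expect_equal(sum(got$low_confidence), 0L)   # strict > never fires on ties

  # large count (outside background range) is never flagged however diffuse
  tab2 <- tab
  tab2$median_nn_distance <- c(100, rep(10, 7))
  tab2$within_background_range[1] <- FALSE
  got2 <- classify_probe_confidence(tab2, n_strata = 2, q = 0.95)
  expect_false(got2$low_confidence[1])

  # raising q never increases the number of flags
  set.seed(56)
  tab3 <- data.frame(
    gene_id = paste0("P", 1:30),
    kind = sample(c("target", "background"), 30, TRUE, prob = c(0.6, 0.4)),
    morans_i_scaled = runif(30),
    median_nn_distance = runif(30, 1, 50),
    within_background_range = sample(c(TRUE, FALSE), 30, TRUE)
  )
  if (!any(tab3$kind == "background")) tab3$kind[1] <- "background"
  flags <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99), function(q) {
    sum(classify_probe_confidence(tab3, n_strata = 3, q = q)$low_confidence)
  }, 0)
  expect_true(all(diff(flags) <= 0))
})

test_that("nuclear fraction is an exact pixel-containment ratio", {
  mask <- two_cell_mask()
  inside <- transcript_table(rep("A", 4),
                             x = c(2.5, 3.5, 6.5, 7.5),
                             y = c(2.5, 3.5, 6.5, 7.5), z = 0)
  expect_equal(nuclear_fraction(inside, mask)$overall, 1)

  zero_mask <- segmentation_mask(matrix(0L, 5, 5), 1)
  expect_equal(nuclear_fraction(inside, zero_mask)$overall, 0)

  mixed <- transcript_table(rep("A", 10),
                            x = c(2.5, 2.7, 3.1, 6.5, 6.7, 7.1, 7.9,
                                  0.5, 0.5, 20),
                            y = c(2.5, 2.7, 3.1, 6.5, 6.7, 7.1, 6.2,
                                  0.5, 9.5, 20), z = 0)
  expect_equal(nuclear_fraction(mixed, mask)$overall, 0.7)
  expect_true(is.na(nuclear_fraction(transcript_table(), mask)$overall))
})

test_that("z histograms flag truncated axial distributions", {
  mid <- transcript_table(rep("A", 50), x = 1:50, y = 1, z = 3)
  expect_false(z_histogram(mid, planes = 7)$truncation_flag)

  tri_counts <- c(1, 5, 9, 12, 9, 5, 1)  # small edges: no flag
  tri <- transcript_table(rep("A", sum(tri_counts)),
                          x = seq_len(sum(tri_counts)), y = 1,
                          z = rep(0:6, times = tri_counts))
  got <- z_histogram(tri, planes = 7)
  expect_equal(got$counts, tri_counts)
  expect_false(got$truncation_flag)

  # truncated-in-z: edge planes at ~80% of the mode
  trunc_counts <- c(8, 9, 10, 10, 10, 9, 8)
  trunc <- transcript_table(rep("A", sum(trunc_counts)),
                            x = seq_len(sum(trunc_counts)), y = 1,
                            z = rep(0:6, times = trunc_counts))
  expect_true(z_histogram(trunc, planes = 7)$truncation_flag)

  not_planes <- transcript_table("A", x = 1, y = 1, z = 2.5)
  expect_error(z_histogram(not_planes, planes = 7), "plane index")
})

test_that("the assembled specificity table separates structure from noise", {
  sim <- simulate_tissue(tissue_sim_config(
    seed = 71L, uniform_target_rates = c(UNIF1 = 80)
  ))
  st <- specificity_table(sim$transcripts, sim$panel, sim$mask)
  bg <- st$kind == "background"
  # background probes sit near the scaled minimum and at Poisson NN spacing
  expect_true(all(st$morans_i_scaled[bg] < 0.2))
  lam <- sim$truth$config$background_rates / 1e6  # calls per um^2
  expected_nn <- sqrt(log(2) / (pi * lam[st$gene_id[bg]]))
  expect_true(all(abs(st$median_nn_distance[bg] / expected_nn - 1) < 0.25))
  # spatially random pseudo-target flagged; rare-cell marker rescued
  expect_true(st$low_confidence[st$gene_id == "UNIF1"])
  expect_true(st$within_background_range[st$gene_id == "CD19"])
  expect_false(st$low_confidence[st$gene_id == "CD19"])
})
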