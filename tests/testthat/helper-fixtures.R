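# Shared fixture builders and independent oracles.

# A small transcript table with uniform positions and a fixed gene alphabet.
random_tt <- function(n, n_genes = 10L, field = c(100, 100), seed = 1L,
                      gene_prefix = "G") {
  set.seed(seed)
  transcript_table(
    gene = paste0(gene_prefix, sample.int(n_genes, n, replace = TRUE)),
    x = runif(n, 0, field[1]),
    y = runif(n, 0, field[2]),
    z = runif(n, 0, 10)
  )
}

# Mask with two square cells (labels 7 and 9) on a 10 x 10 pixel canvas.
two_cell_mask <- function(pixel_size = 1) {
  lab <- matrix(0L, 10L, 10L)
  lab[2:4, 2:4] <- 7L
  lab[6:9, 6:8] <- 9L
  segmentation_mask(lab, pixel_size)
}

# O(n^2) double-sum Moran's I with inverse-distance weights; the direct
# transcription of the statistic used as oracle for the fast path.
moran_oracle <- function(values, centroids) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      w <- 1 / sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      num <- num + w * z[i] * z[j]
      s0 <- s0 + w
    }
  }
  n * num / (s0 * sum(z^2))
}

# Textbook Pearson correlation, written out.
pearson_oracle <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# O(n^2) kNN with the smaller-index tie rule.
knn_oracle <- function(points, k) {
  n <- nrow(points)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((points - matrix(points[i, ], n, 2, byrow = TRUE))^2))
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

# Ten background samples standardised to an exact mean and sd.
exact_bg <- function(mu, sigma, seed = 1L) {
  set.seed(seed)
  v <- rnorm(10L)
  mu + sigma * (v - mean(v)) / sd(v)
}

# Stitch-dedup fixture: dense enough that every gene clears the
# min-occurrence support inside the border window.
dedup_fixture <- function(seed, n = 60000L, n_genes = 15L,
                          field = c(2000, 1000)) {
  random_tt(n, n_genes = n_genes, field = field, seed = seed)
}
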