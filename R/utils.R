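# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic functions route through this so a
# given seed yields bit-identical output regardless of surrounding code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive per-layer child seeds from one parent seed; keeps each simulation
# layer (cells, counts, positions, background, ...) on its own stream.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_istqc <- function(...) {
  stop(..., call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_istqc(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop_istqc(sprintf("`%s` must be > %g", name, lower))
  }
  if (x < lower || x > upper) {
    stop_istqc(sprintf("`%s` must be in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

# Median absolute deviation without the Gaussian consistency constant:
# median(|x_i - median(x)|). Exposed to users via mad_raw() in the image
# metrics module but needed internally elsewhere too.
raw_mad <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

# Pairwise Euclidean distances between two point sets (rows are points).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Per-point nearest-neighbour distance (self excluded). Plane sweep on
# x-sorted points: candidates are examined outward in sort rank, and a
# point is finished once the x-gap to the nearest unexamined rank exceeds
# its current best distance — near-linear for planar point sets, exact in
# all cases.
nn_distances <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop_istqc("nearest-neighbour distances need at least 2 points")
  ord <- order(points[, 1], points[, 2])
  x <- points[ord, 1]
  y <- points[ord, 2]
  best <- rep(Inf, n)
  active <- rep(TRUE, n)
  k <- 0L
  while (any(active) && k < n - 1L) {
    k <- k + 1L
    idx <- which(active)
    for (s in c(-k, k)) {
      j <- idx + s
      ok <- j >= 1L & j <= n
      ii <- idx[ok]
      jj <- j[ok]
      d <- sqrt((x[ii] - x[jj])^2 + (y[ii] - y[jj])^2)
      best[ii] <- pmin(best[ii], d)
    }
    jr <- idx + k + 1L
    jl <- idx - k - 1L
    gap_r <- ifelse(jr <= n, x[pmin(jr, n)] - x[idx], Inf)
    gap_l <- ifelse(jl >= 1L, x[idx] - x[pmax(jl, 1L)], Inf)
    active[idx] <- !(gap_r >= best[idx] & gap_l >= best[idx])
  }
  out <- numeric(n)
  out[ord] <- best
  out
}

# Exact Euclidean k nearest neighbours, ties broken by smaller index.
# Brute force in vectorised chunks; matches an O(n^2) loop oracle exactly.
knn_indices <- function(points, k, chunk = 512L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= k) stop_istqc("need more points than neighbours (n > k)")
  out <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- cross_dist(points[idx, , drop = FALSE], points)
    d[cbind(seq_along(idx), idx)] <- Inf
    for (r in seq_along(idx)) {
      ord <- order(d[r, ], seq_len(n))
      out[idx[r], ] <- ord[seq_len(k)]
    }
  }
  out
}
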