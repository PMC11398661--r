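# Independent reference implementations used as oracles. These deliberately
# use plain loops and direct formula transcription, not the package's code
# paths.

# Kraskov I^(1) by explicit O(N^2) neighbour enumeration.
oracle_mi_knn <- function(a, b, k, metric_b = c("euclidean", "angular")) {
  metric_b <- match.arg(metric_b)
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  N <- ncol(a)
  dist_a <- function(i, j) sqrt(sum((a[, i] - a[, j])^2))
  dist_b <- function(i, j) {
    if (metric_b == "euclidean") sqrt(sum((b[, i] - b[, j])^2))
    else acos(min(1, max(-1, cos(b[1, i] - b[1, j]))))
  }
  total <- 0
  for (i in seq_len(N)) {
    da <- numeric(0); db <- numeric(0)
    for (j in seq_len(N)) {
      if (j == i) next
      da <- c(da, dist_a(i, j))
      db <- c(db, dist_b(i, j))
    }
    dj <- pmax(da, db)
    eps <- sort(dj)[k]
    n_a <- 0; n_b <- 0
    for (j in seq_along(da)) {
      if (da[j] < eps) n_a <- n_a + 1
      if (db[j] < eps) n_b <- n_b + 1
    }
    total <- total + digamma(n_a + 1) + digamma(n_b + 1)
  }
  digamma(k) + digamma(N) - total / N
}

# Local similarity by exhaustive enumeration over every (interval, delay).
oracle_local_similarity <- function(a, b, D) {
  n <- length(a)
  za <- qnorm(rank(a, ties.method = "average") / (n + 1))
  zb <- qnorm(rank(b, ties.method = "average") / (n + 1))
  best <- 0
  for (d in (-D):D) {
    ts <- if (d >= 0) 1:(n - d) else (1 - d):n
    for (s in seq_along(ts)) {
      for (e in s:length(ts)) {
        idx <- ts[s:e]
        best <- max(best, abs(sum(za[idx] * zb[idx + d])))
      }
    }
  }
  best / n
}

# Shift profile and B count by a naive double loop over shifts.
oracle_shift_profile <- function(x, y, r, stat_fn) {
  n <- length(x)
  sapply(-r:r, function(d) stat_fn(x[(1 + r):(n - r)], y[(1 + r + d):(n - r + d)]))
}

oracle_count_b <- function(theta, orientation = "higher_stronger") {
  theta0 <- theta[(length(theta) + 1) / 2]
  if (orientation == "higher_stronger") sum(theta >= theta0) else sum(theta <= theta0)
}

# Mean observed block length in a stationary-bootstrap surrogate of the
# identity series 1..n (block boundaries are where the index does not follow
# its predecessor cyclically).
observed_block_lengths <- function(idx, n) {
  breaks <- c(TRUE, idx[-1] != (idx[-length(idx)] %% n) + 1)
  runs <- diff(c(which(breaks), length(idx) + 1))
  runs
}

# Circularization argmin by exhaustive enumeration of the constrained grid.
oracle_circularize <- function(s, L, kmax) {
  n <- length(s)
  best <- Inf; bk <- c(NA, NA)
  for (k1 in 1:min(kmax, n - L)) {
    for (k2 in max(1, n - L - kmax + 1):(n - L)) {
      if (k2 <= k1) next
      mm <- sum((s[k2 + 0:L] - s[k1 + 0:L])^2)
      if (mm < best) { best <- mm; bk <- c(k1, k2) }
    }
  }
  list(k_start = bk[1], k_end = bk[2], mismatch = best)
}
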