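# Comparator surrogate-data procedures: cyclic permutation, stationary block
# bootstrap, IAAFT, plus circularization preprocessing and the classical
# surrogate-data p-value.

#' Classical surrogate-data p-value
#'
#' `p = (N_as_strong + 1) / (N_surrogates + 1)`, where the count is of
#' surrogate correlations at least as strong as the observed one under the
#' statistic's orientation. The "+1" terms account for the original
#' correlation.
#'
#' @param theta0 observed correlation.
#' @param theta_surr surrogate correlations (at least one).
#' @param orientation `"higher_stronger"` (default) or `"lower_stronger"`.
#' @return p-value in `[1/(N+1), 1]`.
#' @export
surrogate_pvalue <- function(theta0, theta_surr,
                             orientation = c("higher_stronger", "lower_stronger")) {
  orientation <- match.arg(orientation)
  if (length(theta_surr) == 0L) stop("need at least one surrogate value", call. = FALSE)
  n_strong <- if (orientation == "higher_stronger") sum(theta_surr >= theta0)
              else sum(theta_surr <= theta0)
  (n_strong + 1) / (length(theta_surr) + 1)
}

#' Cyclic permutation surrogates
#'
#' All `n - 1` rotations of the series: the k-th surrogate starts at index
#' `k + 1` and wraps around. Deterministic.
#'
#' @param y numeric vector or features-by-time matrix, `n >= 2`.
#' @return list of `n - 1` surrogates (class `surrogate_set`).
#' @examples
#' cyclic_permutations(1:4)  # (2,3,4,1), (3,4,1,2), (4,1,2,3)
#' @export
cyclic_permutations <- function(y) {
  n <- series_length(y)
  if (n < 2L) stop("need a series of length >= 2", call. = FALSE)
  surr <- lapply(seq_len(n - 1L), function(k)
    series_index(y, c((k + 1L):n, 1L:k)))
  structure(list(method = "cyclic", surrogates = surr, params = list(),
                 seed = NULL), class = "surrogate_set")
}

#' Stationary block bootstrap surrogate
#'
#' The stationary bootstrap of random-length blocks: the first index is
#' uniform; at each subsequent step, with probability `p` the surrogate
#' restarts at a fresh uniform index, otherwise it continues to the next
#' index with wrap-around. Block lengths are geometric with mean about `1/p`.
#'
#' @param y numeric vector or features-by-time matrix.
#' @param p restart probability in (0, 1\]; `p = 1` is iid resampling with
#'   replacement.
#' @param seed optional integer seed.
#' @return one surrogate series of the same length.
#' @export
stationary_block_bootstrap <- function(y, p = 0.05, seed = NULL) {
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("p must be in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- series_length(y)
  restart <- c(TRUE, stats::runif(n - 1L) < p)
  fresh <- sample.int(n, sum(restart), replace = TRUE)
  idx <- integer(n)
  j <- 0L
  for (t in seq_len(n)) {
    if (restart[t]) {
      j <- j + 1L
      idx[t] <- fresh[j]
    } else {
      idx[t] <- idx[t - 1L] %% n + 1L
    }
  }
  series_index(y, idx)
}

#' Iterative amplitude-adjusted Fourier transform (IAAFT) surrogate
#'
#' Starts from a random permutation of the series and alternates (i)
#' replacing the Fourier amplitudes with the original amplitudes while
#' keeping the current phases, and (ii) rank-remapping the values onto the
#' sorted original values. After a fixed number of iterations, returns the
#' spectrum-matched iterate (`"true_spectrum"`, amplitude spectrum equal to
#' the original's) or the amplitude-matched iterate (`"true_amplitudes"`, an
#' exact permutation of the original values).
#'
#' @param y univariate numeric vector, `n >= 4`.
#' @param iterations fixed iteration count (default 200; no early exit).
#' @param output `"true_spectrum"` (default) or `"true_amplitudes"`.
#' @param seed optional integer seed.
#' @return one surrogate series of the same length.
#' @export
iaaft <- function(y, iterations = 200L,
                  output = c("true_spectrum", "true_amplitudes"), seed = NULL) {
  output <- match.arg(output)
  if (is.matrix(y) && nrow(y) > 1L)
    stop("IAAFT surrogates are supported for univariate series only", call. = FALSE)
  y <- as_vector_series(y)
  n <- length(y)
  if (n < 4L) stop("need a series of length >= 4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  amp <- Mod(stats::fft(y))
  sorted <- sort(y)
  s <- sample(y)
  s_spec <- s
  for (i in seq_len(iterations)) {
    ft <- stats::fft(s)
    s_spec <- Re(stats::fft(amp * exp(1i * Arg(ft)), inverse = TRUE)) / n
    s <- sorted[rank(s_spec, ties.method = "first")]
  }
  if (output == "true_spectrum") s_spec else s
}

#' Circularize a pair of series before wrap-around surrogate methods
#'
#' Trims both series to a common index range `k_start..(k_end - 1)` chosen to
#' minimize the mismatch \eqn{\sum_{i=0}^{L} (y_{k_2+i} - y_{k_1+i})^2}
#' between the beginning and end of the truncated series, subject to
#' `k_1 <= kmax` and `n - L - k_2 + 1 <= kmax`. The mismatch is evaluated on
#' the series designated by `select_on` (the surrogate source); ties are
#' broken by the lexicographically smallest `(k_1, k_2)`.
#'
#' @param x,y equal-length series.
#' @param L number of overlap points compared (default 10).
#' @param kmax how far from each end the cut points may lie (default 40).
#' @param select_on which series the mismatch is evaluated on.
#' @return list with circularized `x`, `y`, and the chosen `k_start`,
#'   `k_end`, `mismatch`.
#' @export
circularize <- function(x, y, L = 10L, kmax = 40L, select_on = c("y", "x")) {
  select_on <- match.arg(select_on)
  check_equal_length(x, y)
  n <- series_length(x)
  s <- as_vector_series(if (select_on == "y") y else x)
  k1_max <- min(kmax, n - L)
  k2_min <- max(1L, n - L - kmax + 1L)
  k2_max <- n - L
  if (k1_max < 1L || k2_min > k2_max)
    stop("circularization infeasible: series too short for the constraints", call. = FALSE)
  best <- Inf; bk1 <- NA_integer_; bk2 <- NA_integer_
  for (k1 in seq_len(k1_max)) {
    lo <- max(k2_min, k1 + 1L)
    if (lo > k2_max) next
    for (k2 in lo:k2_max) {
      mm <- sum((s[k2 + 0:L] - s[k1 + 0:L])^2)
      if (mm < best) {
        best <- mm; bk1 <- k1; bk2 <- k2
      }
    }
  }
  if (is.na(bk1))
    stop("circularization infeasible: no (k1, k2) pair with k2 > k1", call. = FALSE)
  keep <- bk1:(bk2 - 1L)
  list(x = series_index(x, keep), y = series_index(y, keep),
       k_start = bk1, k_end = bk2, mismatch = best)
}

#' Surrogate-data test for dependence
#'
#' Comparator to [tts_test()]: generates surrogates of one series by cyclic
#' permutation, stationary block bootstrap, or IAAFT, computes the statistic
#' between the other (fixed) series and each surrogate, and returns the
#' classical surrogate-data p-value. Circularization is applied first by
#' default, as recommended for wrap-around methods; both the original and
#' surrogate correlations are then computed from the circularized series.
#'
#' @inheritParams tts_test
#' @param method `"cyclic"`, `"block"`, or `"iaaft"`.
#' @param n_surrogates number of surrogates (default 499); ignored by
#'   `"cyclic"`, which uses all `n - 1` rotations.
#' @param seed integer seed for the stochastic methods.
#' @param circularize_first apply [circularize()] before testing.
#' @param p restart probability for the block bootstrap.
#' @param iterations IAAFT iteration count.
#' @return object of class `surrogate_test`: `p`, `theta0`, `theta_surr`,
#'   `method`, `n_surrogates`, `alpha`, `reject`.
#' @export
surrogate_test <- function(x, y, method = c("cyclic", "block", "iaaft"),
                           stat = stat_pearson(), n_surrogates = 499L,
                           seed = NULL, circularize_first = TRUE,
                           alpha = 0.05, surrogate_from = c("y", "x"),
                           p = 0.05, iterations = 200L) {
  method <- match.arg(method)
  surrogate_from <- match.arg(surrogate_from)
  check_series(x, "x"); check_series(y, "y"); check_equal_length(x, y)
  if (!is.null(seed)) set.seed(seed)
  if (circularize_first) {
    circ <- circularize(x, y, select_on = surrogate_from)
    x <- circ$x; y <- circ$y
  }
  fixed <- if (surrogate_from == "y") x else y
  source <- if (surrogate_from == "y") y else x
  stat_pair <- function(src) {
    if (surrogate_from == "y") stat$fn(fixed, src) else stat$fn(src, fixed)
  }
  theta0 <- as.numeric(stat_pair(source))
  surr <- switch(method,
    cyclic = cyclic_permutations(source)$surrogates,
    block = lapply(seq_len(n_surrogates), function(i)
      stationary_block_bootstrap(source, p = p)),
    iaaft = lapply(seq_len(n_surrogates), function(i)
      iaaft(source, iterations = iterations)))
  theta_surr <- vapply(surr, function(s) as.numeric(stat_pair(s)), numeric(1))
  pv <- surrogate_pvalue(theta0, theta_surr, stat$orientation)
  structure(list(p = pv, theta0 = theta0, theta_surr = theta_surr,
                 method = method, n_surrogates = length(theta_surr),
                 statistic = stat$name, alpha = alpha, reject = (pv <= alpha),
                 circularized = circularize_first,
                 surrogate_from = surrogate_from),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("Surrogate-data test (%s, %d surrogates%s)\n", x$method,
              x$n_surrogates, if (x$circularized) ", circularized" else ""))
  cat(sprintf("  statistic: %s, theta0 = %.6g\n", x$statistic, x$theta0))
  cat(sprintf("  p = %.6g; %s at alpha = %g\n", x$p,
              if (x$reject) "dependence detected" else "no dependence detected",
              x$alpha))
  invisible(x)
}
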