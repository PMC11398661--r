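# Truncated time-shift (TTS) test engine.
#
# The test deletes r points from each end of x, slides a same-length window
# of y across shifts delta = -r..r, computes a correlation statistic at every
# shift, counts the shifts B whose correlation is at least as strong as the
# unshifted one, and thresholds u = B/(r+1). Under independence, with the
# shifted series strict-sense stationary, P(u <= alpha) <= alpha.

#' Truncate a time series
#'
#' Deletes `r` time points from each end, returning
#' \eqn{\{x_{1+r}, \dots, x_{n-r}\}} of length `n - 2r`.
#'
#' @param x numeric vector or features-by-time matrix.
#' @param r nonnegative integer truncation radius; requires `n > 2r`.
#' @return the truncated series (same representation as the input).
#' @examples
#' tts_truncate(1:4, 1)   # -> 2 3
#' @export
tts_truncate <- function(x, r) {
  n <- series_length(x)
  r <- check_radius(r)
  if (n <= 2 * r)
    stop(sprintf("invalid radius: need n > 2r but n = %d, r = %d", n, r), call. = FALSE)
  series_index(x, (1 + r):(n - r))
}

#' Shifted window of a time series
#'
#' Returns \eqn{\{y_{1+r+\delta}, \dots, y_{n-r+\delta}\}}, the window with
#' the same length as `tts_truncate(x, r)` displaced by `delta` steps. At
#' `delta = 0` this is the aligned original window.
#'
#' @param y numeric vector or features-by-time matrix.
#' @param r truncation radius.
#' @param delta integer shift with `|delta| <= r`.
#' @return the shifted window.
#' @examples
#' tts_shift(1:4, 1, 1)    # -> 3 4
#' tts_shift(1:4, 1, -1)   # -> 1 2
#' @export
tts_shift <- function(y, r, delta) {
  n <- series_length(y)
  r <- check_radius(r)
  if (abs(delta) > r)
    stop(sprintf("invalid shift: need |delta| <= r but delta = %d, r = %d",
                 delta, r), call. = FALSE)
  if (n <= 2 * r)
    stop(sprintf("invalid radius: need n > 2r but n = %d, r = %d", n, r), call. = FALSE)
  series_index(y, (1 + r + delta):(n - r + delta))
}

check_radius <- function(r) {
  if (length(r) != 1L || is.na(r) || r < 0 || r != round(r))
    stop("truncation radius must be a single nonnegative integer", call. = FALSE)
  as.integer(r)
}

#' Correlations across all shifts
#'
#' Computes `theta[delta] = stat(tts_truncate(x, r), tts_shift(y, r, delta))`
#' for every shift `delta` in `-r..r` (or, with `shift = "x"`, slides the x
#' window against the truncated y). The univariate Pearson-strength statistic
#' takes a vectorized path (all windows gathered into one matrix and
#' correlated in a single call); the result is identical to the per-shift
#' loop.
#'
#' @param x,y equal-length series.
#' @param r truncation radius.
#' @param stat a statistic created by [tts_stat()] or one of the `stat_*`
#'   constructors.
#' @param shift which series is slid to generate surrogates (`"y"` default).
#' @return an object of class `shift_profile`: list with `r`, `shifts`,
#'   `theta`, `orientation`, `statistic`.
#' @examples
#' x <- sin(1:60 / 3); shift_profile(x, x, 2, stat_pearson())
#' @export
shift_profile <- function(x, y, r, stat = stat_pearson(), shift = c("y", "x")) {
  shift <- match.arg(shift)
  check_series(x, "x"); check_series(y, "y"); check_equal_length(x, y)
  r <- check_radius(r)
  n <- series_length(x)
  if (n <= 2 * r)
    stop(sprintf("invalid radius: need n > 2r but n = %d, r = %d", n, r), call. = FALSE)
  shifts <- (-r):r
  if (identical(stat$name, "pearson") && is_univariate(x) && is_univariate(y)) {
    theta <- pearson_profile_fast(as_vector_series(x), as_vector_series(y), r, shift)
  } else {
    fixed <- if (shift == "y") tts_truncate(x, r) else tts_truncate(y, r)
    moving <- if (shift == "y") y else x
    theta <- vapply(shifts, function(d) {
      win <- tts_shift(moving, r, d)
      val <- tryCatch(
        if (shift == "y") stat$fn(fixed, win) else stat$fn(win, fixed),
        error = function(e) stop(sprintf("statistic '%s' failed at shift delta = %d: %s",
                                         stat$name, d, conditionMessage(e)), call. = FALSE))
      as.numeric(val)
    }, numeric(1))
  }
  structure(list(r = r, shifts = shifts, theta = theta,
                 orientation = stat$orientation, statistic = stat$name),
            class = "shift_profile")
}

# All shifted windows as columns of one matrix; |cor| in a single call.
pearson_profile_fast <- function(x, y, r, shift = "y") {
  n <- length(x)
  len <- n - 2L * r
  if (len < 3L)
    stop("windows must have length >= 3; reduce the truncation radius", call. = FALSE)
  shifts <- (-r):r
  if (shift == "y") {
    fixed <- x[(1 + r):(n - r)]
    moving <- y
  } else {
    fixed <- y[(1 + r):(n - r)]
    moving <- x
  }
  idx <- outer(seq_len(len) + r, shifts, `+`)
  w <- matrix(moving[idx], nrow = len)
  if (stats::sd(fixed) == 0) stop("degenerate window: zero variance", call. = FALSE)
  sds <- apply(w, 2L, stats::sd)
  if (any(sds == 0)) {
    d <- shifts[which(sds == 0)[1L]]
    stop(sprintf("statistic 'pearson' failed at shift delta = %d: degenerate window: zero variance", d),
         call. = FALSE)
  }
  as.numeric(abs(stats::cor(fixed, w)))
}

#' Count shifts at least as strong as the unshifted correlation
#'
#' `B` counts the shifts (the unshifted one included, so `B >= 1`) whose
#' correlation is at least as strong as at `delta = 0`. Orientation
#' `"higher_stronger"` uses `>=`; `"lower_stronger"` (error-like statistics)
#' uses `<=`. Comparisons are exact; floating-point ties count as ties, which
#' inflates `B` and is conservative.
#'
#' @param profile a `shift_profile`.
#' @return integer `B` in `1..(2r+1)`.
#' @export
count_b <- function(profile) {
  stopifnot(inherits(profile, "shift_profile"))
  theta0 <- profile$theta[profile$shifts == 0L]
  if (profile$orientation == "higher_stronger")
    sum(profile$theta >= theta0)
  else
    sum(profile$theta <= theta0)
}

#' The TTS u statistic
#'
#' `u = B/(r+1)`. Although `u` can exceed 1, it is superuniform under the
#' independence null when the shifted series is stationary, so thresholding
#' `u <= alpha` keeps the false positive rate at or below `alpha`.
#'
#' @param B integer count of shifts at least as strong as the unshifted one.
#' @param r truncation radius.
#' @return `B/(r+1)`.
#' @examples
#' u_statistic(1, 19)   # 0.05
#' u_statistic(2, 38)   # 2/39, just above 0.05
#' @export
u_statistic <- function(B, r) {
  check_b(B, r)
  B / (r + 1)
}

#' The naive time-shift p-value
#'
#' `p_naive = B/(2r+1)`, the classical surrogate-data proportion. It is not a
#' valid p-value because shifted surrogates are mutually dependent, but its
#' false positive rate exceeds the nominal level by less than a factor of 2
#' (the ratio `u/p_naive = (2r+1)/(r+1) < 2`).
#'
#' @inheritParams u_statistic
#' @return `B/(2r+1)`.
#' @export
naive_p <- function(B, r) {
  check_b(B, r)
  B / (2 * r + 1)
}

check_b <- function(B, r) {
  r <- check_radius(r)
  if (length(B) != 1L || is.na(B) || B != round(B) || B < 1 || B > 2 * r + 1)
    stop(sprintf("B must be an integer in 1..(2r+1); got B = %s, r = %d",
                 format(B), r), call. = FALSE)
  invisible(NULL)
}

#' Pre-shift a pair of series by a hypothesized coupling lag
#'
#' The lag-`l` test aligns a hypothesized coupling delay before testing: for
#' `l >= 0` it pairs \eqn{\{x_{1+l},\dots,x_n\}} with
#' \eqn{\{y_1,\dots,y_{n-l}\}}; negative `l` shifts the other way. The lag
#' must come from a mechanistic hypothesis or independent pilot data, never
#' from the tested series themselves (scanning lags on the same data makes
#' rejection certain).
#'
#' @param x,y equal-length series.
#' @param l integer lag, `|l| < n`.
#' @return list with components `x` and `y`, both of length `n - |l|`.
#' @export
lag_preshift <- function(x, y, l) {
  check_equal_length(x, y)
  n <- series_length(x)
  if (length(l) != 1L || is.na(l) || l != round(l) || abs(l) >= n)
    stop(sprintf("invalid lag: need |l| < n but l = %s, n = %d", format(l), n),
         call. = FALSE)
  l <- as.integer(l)
  if (l >= 0L)
    list(x = series_index(x, (1 + l):n), y = series_index(y, 1:(n - l)))
  else
    list(x = series_index(x, 1:(n + l)), y = series_index(y, (1 - l):n))
}

#' Truncated time-shift test for dependence between two time series
#'
#' Tests the null hypothesis that `{x_t}` and `{y_t}` are statistically
#' independent. The test is valid (false positive rate at most `alpha`)
#' whenever the series designated by `surrogate_from` is strict-sense
#' stationary, for any correlation statistic.
#'
#' @param x,y equal-length numeric vectors or features-by-time matrices.
#' @param r truncation radius: `r` points are removed from each end and the
#'   `2r` shifted windows serve as surrogates. Power is maximized at radii of
#'   the form `j/alpha - 1` (see [optimal_radius()]).
#' @param stat correlation statistic (default Pearson strength).
#' @param lag hypothesized coupling lag applied via [lag_preshift()] before
#'   testing; must not be estimated from the tested data.
#' @param alpha significance level.
#' @param surrogate_from which series is shifted to generate surrogates
#'   (`"y"` default); validity requires only this series to be stationary.
#' @return object of class `tts_result` with fields `B`, `r`, `u`,
#'   `p` (`= min(u, 1)`), `lag`, `alpha`, `reject` (`u <= alpha`),
#'   `statistic`, `orientation`, `surrogate_from`, and the `profile`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.5), 200))
#' y <- as.numeric(arima.sim(list(ar = 0.5), 200))
#' tts_test(x, y, r = 19)
#' @export
tts_test <- function(x, y, r, stat = stat_pearson(), lag = 0L, alpha = 0.05,
                     surrogate_from = c("y", "x")) {
  surrogate_from <- match.arg(surrogate_from)
  check_series(x, "x"); check_series(y, "y"); check_equal_length(x, y)
  pre <- lag_preshift(x, y, lag)
  n <- series_length(pre$x)
  r <- check_radius(r)
  if (n <= 2 * r)
    stop(sprintf("invalid radius: need n > 2r after lag pre-shift (n = %d, r = %d)",
                 n, r), call. = FALSE)
  if (r > n / 3)
    warning(sprintf("truncation radius r = %d exceeds a third of the series length %d; the test probes dependence with a short central window only", r, n))
  profile <- shift_profile(pre$x, pre$y, r, stat,
                           shift = if (surrogate_from == "y") "y" else "x")
  B <- count_b(profile)
  u <- u_statistic(B, r)
  structure(list(B = B, r = r, u = u, p = min(u, 1), naive_p = naive_p(B, r),
                 lag = as.integer(lag), alpha = alpha, reject = (u <= alpha),
                 statistic = stat$name, orientation = stat$orientation,
                 surrogate_from = surrogate_from, n = n, profile = profile),
            class = "tts_result")
}

#' @export
print.tts_result <- function(x, ...) {
  cat("Truncated time-shift (TTS) test\n")
  cat(sprintf("  statistic: %s (%s), surrogates from %s, lag = %d\n",
              x$statistic, x$orientation, x$surrogate_from, x$lag))
  cat(sprintf("  r = %d (%d surrogates), B = %d\n", x$r, 2 * x$r, x$B))
  cat(sprintf("  u = B/(r+1) = %.6g, reported p = min(u,1) = %.6g\n", x$u, x$p))
  cat(sprintf("  %s at alpha = %g\n",
              if (x$reject) "dependence detected" else "no dependence detected",
              x$alpha))
  invisible(x)
}

#' Multi-lag TTS test with Bonferroni correction
#'
#' Runs the lag-`l` TTS test at each lag in `lags` and reports dependence if
#' any lag is significant at the `alpha/m` level (`m = length(lags)`). The
#' Bonferroni correction preserves validity.
#'
#' @inheritParams tts_test
#' @param lags distinct integer lags to test.
#' @return object of class `tts_multilag`: `lags`, `per_lag` (list of
#'   `tts_result`), `alpha`, `reject`.
#' @export
multi_lag_tts <- function(x, y, r, stat = stat_pearson(), lags = 0L,
                          alpha = 0.05, surrogate_from = c("y", "x")) {
  surrogate_from <- match.arg(surrogate_from)
  if (anyDuplicated(lags)) stop("lags must be distinct", call. = FALSE)
  m <- length(lags)
  per_lag <- lapply(lags, function(l)
    tts_test(x, y, r, stat, lag = l, alpha = alpha / m,
             surrogate_from = surrogate_from))
  structure(list(lags = as.integer(lags), per_lag = per_lag, alpha = alpha,
                 m = m, reject = any(vapply(per_lag, function(z) z$u, 0) <= alpha / m)),
            class = "tts_multilag")
}

#' @export
print.tts_multilag <- function(x, ...) {
  cat(sprintf("Multi-lag TTS test: %d lags, per-lag level alpha/m = %g\n",
              x$m, x$alpha / x$m))
  u <- vapply(x$per_lag, function(z) z$u, 0)
  cat(sprintf("  lag %3d: u = %.6g%s\n", x$lags, u,
              ifelse(u <= x$alpha / x$m, "  *", "")), sep = "")
  cat(sprintf("  %s at alpha = %g\n",
              if (x$reject) "dependence detected" else "no dependence detected",
              x$alpha))
  invisible(x)
}

#' Power-maximizing truncation radius
#'
#' For `m` Bonferroni-corrected lags at level `alpha`, power is maximized at
#' radii of the form `r = j m / alpha - 1` for a positive integer `j`: any
#' radius between two such values requires the same `B` but discards more
#' data.
#'
#' @param alpha significance level in (0, 1).
#' @param m number of lags tested (1 for a single test).
#' @param j positive integer multiplier; larger `j` gives more surrogates but
#'   shorter windows.
#' @return integer radius `j*m/alpha - 1` (rounded, with a warning, if
#'   `j*m/alpha` is not an integer).
#' @examples
#' optimal_radius(0.05)          # 19
#' optimal_radius(0.05, m = 5)   # 99
#' @export
optimal_radius <- function(alpha, m = 1L, j = 1L) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (m < 1 || j < 1) stop("j and m must be positive integers", call. = FALSE)
  raw <- j * m / alpha - 1
  r <- round(raw)
  if (abs(raw - r) > 1e-8)
    warning(sprintf("j*m/alpha = %.6g is not an integer; rounding radius to %d",
                    j * m / alpha, as.integer(r)))
  as.integer(r)
}

#' Default truncation radius for a series of length n
#'
#' Picks the largest radius on the power-optimal lattice `j*m/alpha - 1` that
#' stays at or below a fifth of the series length (small radii, under 20% of
#' the length, tend to win for short series), but never less than
#' `m/alpha - 1`, the smallest usable radius.
#'
#' @param n series length.
#' @param alpha significance level.
#' @param m number of lags to be tested.
#' @return integer radius.
#' @examples
#' default_radius(400, 0.05)  # 79
#' default_radius(100, 0.05)  # 19
#' @export
default_radius <- function(n, alpha = 0.05, m = 1L) {
  base <- m / alpha
  rmin <- round(base) - 1
  if (n <= 2 * rmin)
    stop(sprintf("insufficient data: testing %d lag(s) at alpha = %g needs length > %d",
                 m, alpha, 2 * rmin + 1), call. = FALSE)
  jmax <- floor((floor(n / 5) + 1) / base)
  as.integer(max(rmin, jmax * round(base) - 1))
}

#' Detrend-retrend TTS test for trend-nonstationary series
#'
#' For series decomposable into a deterministic trend plus a stationary
#' component: (1) remove the fitted trend from the surrogate-source series;
#' (2) generate time-shifted surrogates from the stationary residual;
#' (3) add the truncated trend back to each surrogate. The zero-shift
#' surrogate reproduces the original truncated series exactly, so with a zero
#' trend the test reduces to [tts_test()].
#'
#' @inheritParams tts_test
#' @param trend_fitter either a nonnegative integer (degree of an ordinary
#'   least-squares polynomial fit in time, default 1) or a function mapping a
#'   numeric series to a same-length deterministic trend.
#' @return a `tts_result` (with `detrended = TRUE` recorded).
#' @export
detrend_retrend_tts <- function(x, y, r, stat = stat_pearson(),
                                trend_fitter = 1L, alpha = 0.05) {
  check_series(x, "x"); check_series(y, "y"); check_equal_length(x, y)
  if (!is_univariate(y))
    stop("detrend-retrend is implemented for univariate surrogate series", call. = FALSE)
  yv <- as_vector_series(y)
  n <- length(yv)
  r <- check_radius(r)
  if (n <= 2 * r)
    stop(sprintf("invalid radius: need n > 2r but n = %d, r = %d", n, r), call. = FALSE)
  trend <- if (is.function(trend_fitter)) {
    tr <- trend_fitter(yv)
    if (length(tr) != n) stop("trend_fitter must return a trend of equal length", call. = FALSE)
    tr
  } else {
    fit_poly_trend(yv, degree = as.integer(trend_fitter))
  }
  resid <- yv - trend
  tr_trunc <- trend[(1 + r):(n - r)]
  shifts <- (-r):r
  xt <- if (is_univariate(x)) as_vector_series(x)[(1 + r):(n - r)] else tts_truncate(x, r)
  if (identical(stat$name, "pearson") && is_univariate(x)) {
    len <- n - 2L * r
    idx <- outer(seq_len(len) + r, shifts, `+`)
    w <- matrix(resid[idx], nrow = len) + tr_trunc
    if (stats::sd(xt) == 0) stop("degenerate window: zero variance", call. = FALSE)
    theta <- as.numeric(abs(stats::cor(xt, w)))
  } else {
    theta <- vapply(shifts, function(d) {
      surro <- tts_shift(resid, r, d) + tr_trunc
      as.numeric(stat$fn(xt, surro))
    }, numeric(1))
  }
  profile <- structure(list(r = r, shifts = shifts, theta = theta,
                            orientation = stat$orientation, statistic = stat$name),
                       class = "shift_profile")
  B <- count_b(profile)
  u <- u_statistic(B, r)
  structure(list(B = B, r = r, u = u, p = min(u, 1), naive_p = naive_p(B, r),
                 lag = 0L, alpha = alpha, reject = (u <= alpha),
                 statistic = stat$name, orientation = stat$orientation,
                 surrogate_from = "y", n = n, detrended = TRUE,
                 profile = profile),
            class = "tts_result")
}

fit_poly_trend <- function(v, degree = 1L) {
  if (degree < 0) stop("polynomial degree must be nonnegative", call. = FALSE)
  t <- seq_along(v)
  if (degree == 0L) return(rep(mean(v), length(v)))
  as.numeric(stats::fitted(stats::lm(v ~ stats::poly(t, degree, raw = TRUE))))
}

#' Benjamini-Hochberg adjustment for superuniform p-values
#'
#' Clips values at 1 (TTS `u` statistics may exceed 1) and applies the
#' standard step-up false discovery rate adjustment.
#'
#' @param p numeric vector of p-values or `u` statistics (nonnegative).
#' @return adjusted values, same length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0)) stop("p-values must be nonnegative", call. = FALSE)
  stats::p.adjust(pmin(p, 1), method = "BH")
}
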