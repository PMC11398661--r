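# Pluggable correlation statistics. A statistic is a pure function of its two
# input windows together with an orientation flag: "higher_stronger" for
# similarity-like statistics, "lower_stronger" for error-like statistics
# (e.g., a mean squared error), for which the shift-counting comparison is
# inverted rather than the values negated, keeping reported theta
# interpretable.

#' Define a correlation statistic
#'
#' @param name short identifier used in printed output and dispatch.
#' @param fn function of two windows (numeric vectors, or features-by-time
#'   matrices for multivariate statistics) returning a single number. Must be
#'   deterministic and free of hidden state.
#' @param orientation `"higher_stronger"` or `"lower_stronger"`.
#' @param params named list of parameters, recorded for output metadata.
#' @param symmetric logical; whether `fn(a, b) == fn(b, a)`.
#' @return an object of class `tts_stat`.
#' @export
tts_stat <- function(name, fn, orientation = c("higher_stronger", "lower_stronger"),
                     params = list(), symmetric = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(is.function(fn), is.character(name), length(name) == 1L)
  structure(list(name = name, fn = fn, orientation = orientation,
                 params = params, symmetric = symmetric),
            class = "tts_stat")
}

#' @export
print.tts_stat <- function(x, ...) {
  p <- if (length(x$params)) paste0(" (", paste(names(x$params), unlist(x$params),
                                                sep = "=", collapse = ", "), ")") else ""
  cat(sprintf("statistic '%s'%s, %s\n", x$name, p, x$orientation))
  invisible(x)
}

#' Pearson correlation strength
#'
#' The absolute value of the sample Pearson correlation coefficient.
#'
#' @param a,b equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return value in \[0, 1\].
#' @export
pearson_strength <- function(a, b) {
  a <- as_vector_series(a); b <- as_vector_series(b)
  if (length(a) != length(b)) stop("windows must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("windows must have length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate window: zero variance", call. = FALSE)
  abs(stats::cor(a, b))
}

#' @rdname pearson_strength
#' @export
stat_pearson <- function() {
  tts_stat("pearson", pearson_strength, "higher_stronger", symmetric = TRUE)
}

#' Angular distance between two angles
#'
#' `arccos(cos(alpha - beta))`, the shorter arc between two angles: 0.1*pi*
#' and 1.9*pi* are 0.2*pi* apart, not 1.8*pi*.
#'
#' @param alpha,beta angles in radians (any real values; recycled).
#' @return distances in \[0, pi\].
#' @export
angular_distance <- function(alpha, beta) {
  acos(pmin(1, pmax(-1, cos(alpha - beta))))
}

# N x N distance matrix on a marginal space. Input: d x N matrix (rows =
# coordinates, columns = observations) or a numeric vector.
marginal_dist <- function(m, metric) {
  if (is.function(metric)) return(metric(m))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  switch(metric,
    euclidean = as.matrix(stats::dist(t(m))),
    angular = {
      if (nrow(m) != 1L) stop("angular metric applies to univariate angles", call. = FALSE)
      v <- as.numeric(m)
      outer(v, v, angular_distance)
    },
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

#' k-nearest-neighbour mutual information (Kraskov estimator I^(1))
#'
#' Estimates the mutual information (in nats) between two variables from
#' paired samples: \eqn{I = \psi(k) + \psi(N) - \langle \psi(n_a+1) +
#' \psi(n_b+1) \rangle}, where the joint space uses the maximum of the two
#' marginal distances, \eqn{\epsilon_i} is each point's distance to its k-th
#' joint neighbour, and \eqn{n_a, n_b} count marginal neighbours strictly
#' within \eqn{\epsilon_i}.
#'
#' @param a,b paired samples: numeric vectors or d-by-N matrices (columns are
#'   observations).
#' @param k number of neighbours (default 3).
#' @param metric_a,metric_b `"euclidean"`, `"angular"`, or a function mapping
#'   the marginal sample to an N-by-N distance matrix.
#' @return estimated mutual information in nats (can be slightly negative for
#'   independent samples).
#' @export
mi_knn <- function(a, b, k = 3L, metric_a = "euclidean", metric_b = "euclidean") {
  na <- if (is.matrix(a)) ncol(a) else length(a)
  nb <- if (is.matrix(b)) ncol(b) else length(b)
  if (na != nb) stop("samples must be paired (equal N)", call. = FALSE)
  N <- na
  if (N <= k) stop(sprintf("insufficient data: need N > k (N = %d, k = %d)", N, k),
                   call. = FALSE)
  da <- marginal_dist(a, metric_a)
  db <- marginal_dist(b, metric_b)
  dj <- pmax(da, db)
  terms <- vapply(seq_len(N), function(i) {
    d <- dj[i, -i]
    eps <- sort(d, partial = k)[k]
    n_a <- sum(da[i, -i] < eps)
    n_b <- sum(db[i, -i] < eps)
    digamma(n_a + 1) + digamma(n_b + 1)
  }, numeric(1))
  digamma(k) + digamma(N) - mean(terms)
}

#' @rdname mi_knn
#' @export
stat_mi <- function(k = 3L) {
  force(k)
  tts_stat("mi", function(a, b) mi_knn(a, b, k = k), "higher_stronger",
           params = list(k = k), symmetric = TRUE)
}

#' Mutual information between a linear and a circular variable
#'
#' [mi_knn()] with Euclidean distance on the first variable (e.g., speed) and
#' angular distance on the second (e.g., direction of motion in radians).
#'
#' @param linear numeric vector.
#' @param angle vector of angles in radians.
#' @param k number of neighbours.
#' @return estimated mutual information in nats.
#' @export
mi_circular <- function(linear, angle, k = 3L) {
  mi_knn(linear, angle, k = k, metric_a = "euclidean", metric_b = "angular")
}

#' @rdname mi_circular
#' @export
stat_mi_circular <- function(k = 3L) {
  force(k)
  tts_stat("mi_circular", function(a, b) mi_circular(a, b, k = k),
           "higher_stronger", params = list(k = k))
}

#' Local similarity score
#'
#' Detects transient correlations: both series are normal-score transformed
#' (average ranks mapped to Gaussian quantiles), and the score is the maximal
#' absolute partial sum of aligned products over all contiguous intervals and
#' delays `|d| <= D`, divided by `n`. Computed by the standard dynamic
#' program over maximal positive and negative running sums.
#'
#' @param a,b equal-length numeric vectors, `n >= 3`.
#' @param D maximum delay (default 0).
#' @return the local similarity score (sign-symmetric in either argument).
#' @export
local_similarity <- function(a, b, D = 0L) {
  a <- as_vector_series(a); b <- as_vector_series(b)
  n <- length(a)
  if (length(b) != n) stop("windows must have equal length", call. = FALSE)
  if (n < 3L) stop("windows must have length >= 3", call. = FALSE)
  if (D < 0 || D >= n) stop("delay bound D must satisfy 0 <= D < n", call. = FALSE)
  za <- stats::qnorm(rank(a, ties.method = "average") / (n + 1))
  zb <- stats::qnorm(rank(b, ties.method = "average") / (n + 1))
  best <- 0
  for (d in (-D):D) {
    ta <- if (d >= 0) seq_len(n - d) else seq(1 - d, n)
    prods <- za[ta] * zb[ta + d]
    pos <- 0; neg <- 0
    for (p in prods) {
      pos <- max(0, pos + p)
      neg <- max(0, neg - p)
      best <- max(best, pos, neg)
    }
  }
  best / n
}

#' @rdname local_similarity
#' @export
stat_local_similarity <- function(D = 0L) {
  force(D)
  tts_stat("lsa", function(a, b) local_similarity(a, b, D = D),
           "higher_stronger", params = list(D = D))
}

#' Cross-map skill
#'
#' Builds the delay embedding of `x` with dimension `E` and lag `tau`, and
#' for each embedded point predicts the contemporaneous `y` value from its
#' `E + 1` nearest embedded neighbours (self excluded) with exponential
#' weights `exp(-d_i/d_1)`; zero nearest distance falls back to indicator
#' weights on the zero-distance neighbours. Skill is the Pearson correlation
#' between predictions and observations. High skill when predicting `y` from
#' the `x` embedding indicates that `y` influences `x`.
#'
#' @param x predictor series (its embedding is used).
#' @param y target series.
#' @param E embedding dimension (default 2).
#' @param tau embedding lag (default 1).
#' @return the cross-map correlation.
#' @export
cross_map_skill <- function(x, y, E = 2L, tau = 1L) {
  x <- as_vector_series(x); y <- as_vector_series(y)
  n <- length(x)
  if (length(y) != n) stop("windows must have equal length", call. = FALSE)
  if (E < 1 || tau < 1) stop("E and tau must be positive integers", call. = FALSE)
  if (n <= (E - 1) * tau + E + 2)
    stop("series too short for this embedding", call. = FALSE)
  times <- ((E - 1) * tau + 1):n
  emb <- vapply(0:(E - 1), function(j) x[times - j * tau], numeric(length(times)))
  if (E == 1L) emb <- matrix(emb, ncol = 1L)
  dmat <- as.matrix(stats::dist(emb))
  if (max(dmat) == 0)
    stop("degenerate embedding: constant predictor series", call. = FALSE)
  m <- length(times)
  k <- E + 1L
  pred <- vapply(seq_len(m), function(i) {
    d <- dmat[i, ]
    d[i] <- Inf
    ord <- order(d)[seq_len(k)]
    d1 <- d[ord[1L]]
    if (!is.finite(d1)) stop("degenerate embedding", call. = FALSE)
    w <- if (d1 == 0) {
      zero <- d[ord] == 0
      as.numeric(zero)
    } else {
      exp(-d[ord] / d1)
    }
    w <- w / sum(w)
    sum(w * y[times[ord]])
  }, numeric(1))
  obs <- y[times]
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("degenerate window: zero variance", call. = FALSE)
  stats::cor(pred, obs)
}

#' @rdname cross_map_skill
#' @export
stat_cross_map <- function(E = 2L, tau = 1L) {
  force(E); force(tau)
  tts_stat("ccm", function(a, b) cross_map_skill(a, b, E = E, tau = tau),
           "higher_stronger", params = list(E = E, tau = tau))
}

#' Median statistic over shared features
#'
#' For two features-by-time matrices, computes a base statistic per feature
#' ID shared between them (exact string match on rownames) and returns the
#' median; with an even number of shared features this is the mean of the two
#' central order statistics. Gives the cross-site correlation of the
#' "typical" feature, avoiding one test per feature.
#'
#' @param X,Y features-by-time numeric matrices with rownames as feature IDs.
#' @param base base statistic applied per shared feature (default Pearson
#'   strength).
#' @return the median of the per-feature statistics.
#' @export
median_feature_statistic <- function(X, Y, base = stat_pearson()) {
  if (!is.matrix(X) || !is.matrix(Y) || is.null(rownames(X)) || is.null(rownames(Y)))
    stop("X and Y must be matrices with feature IDs as rownames", call. = FALSE)
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) == 0L) stop("no shared features between X and Y", call. = FALSE)
  vals <- vapply(shared, function(f) base$fn(X[f, ], Y[f, ]), numeric(1))
  stats::median(vals)
}

#' @rdname median_feature_statistic
#' @export
stat_median_feature <- function(base = stat_pearson()) {
  force(base)
  tts_stat(paste0("median-", base$name),
           function(a, b) median_feature_statistic(a, b, base = base),
           base$orientation, params = base$params, symmetric = base$symmetric)
}

#' Fold a circular direction onto \[0, 1\]
#'
#' `|sin(phi)|`: largest (1) at 90 or 270 degrees, smallest (0) at 0 or 180
#' degrees. Makes a linear correlation meaningful for a direction variable
#' whose relevant contrast is tangential versus radial motion.
#'
#' @param phi angles in radians.
#' @return `abs(sin(phi))`, elementwise.
#' @export
sin_mod_transform <- function(phi) {
  abs(sin(phi))
}
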