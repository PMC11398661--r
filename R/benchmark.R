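# Experiment harness: false-positive-rate and power studies over
# (system, test, statistic) grids with deterministic per-trial seeding.

#' Deterministic per-trial seed
#'
#' Derives the seed for one trial from a master seed and the trial index by a
#' fixed affine map modulo 2^31 - 1, so grids are reproducible and trials are
#' independent streams.
#'
#' @param master_seed integer master seed.
#' @param index trial index (vectorized).
#' @return integer seed(s) in `[0, 2^31 - 2]`.
#' @export
trial_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + as.double(index) * 9973) %% 2147483647)
}

#' Wilson 95% confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named vector `c(low, high)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

# generator dispatch: system id -> function(n, seed, params) -> series
system_generator <- function(system) {
  gens <- list(
    ar1 = function(n, seed, p) do.call(simulate_ar1, c(list(n = n, seed = seed), p)),
    logistic = function(n, seed, p) do.call(simulate_logistic, c(list(n = n, seed = seed), p)),
    sine_sawtooth = function(n, seed, p) do.call(simulate_sine_sawtooth, c(list(n = n, seed = seed), p)),
    sine_threshold = function(n, seed, p) do.call(simulate_sine_threshold, c(list(n = n, seed = seed), p)),
    coin = function(n, seed, p) do.call(simulate_autocorrelated_coin, c(list(n = n, seed = seed), p)),
    growth_collapse = function(n, seed, p) do.call(simulate_growth_collapse, c(list(n = n, seed = seed), p)),
    fitzhugh_nagumo = function(n, seed, p) do.call(simulate_fitzhugh_nagumo, c(list(n = n, seed = seed), p)),
    lotka_volterra = function(n, seed, p) do.call(simulate_lotka_volterra, c(list(n = n, seed = seed), p)),
    random_walk = function(n, seed, p) do.call(simulate_random_walk, c(list(n = n, seed = seed), p)),
    trended_ar1 = function(n, seed, p) {
      p$trend_slope <- p$trend_slope %||% 0.01
      do.call(simulate_ar1, c(list(n = n, seed = seed), p))
    })
  g <- gens[[system]]
  if (is.null(g)) stop(sprintf("unknown system '%s'", system), call. = FALSE)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one decision under the configured test
run_one_test <- function(x, y, test, stat, r, alpha, lag, lags, trial_seed_value,
                         detrend_degree = NULL, n_surrogates = 99L) {
  switch(test,
    tts = tts_test(x, y, r, stat, lag = lag, alpha = alpha)$reject,
    naive_tts = {
      res <- tts_test(x, y, r, stat, lag = lag, alpha = alpha)
      res$naive_p <= alpha
    },
    multi_lag_tts = multi_lag_tts(x, y, r, stat, lags = lags, alpha = alpha)$reject,
    detrend_tts = detrend_retrend_tts(x, y, r, stat,
                                      trend_fitter = detrend_degree %||% 1L,
                                      alpha = alpha)$reject,
    cyclic = surrogate_test(x, y, "cyclic", stat, alpha = alpha,
                            seed = trial_seed_value)$reject,
    block = surrogate_test(x, y, "block", stat, alpha = alpha,
                           n_surrogates = n_surrogates,
                           seed = trial_seed_value)$reject,
    iaaft = surrogate_test(x, y, "iaaft", stat, alpha = alpha,
                           n_surrogates = n_surrogates,
                           seed = trial_seed_value)$reject,
    parametric = corrected_pearson_test(x, y, alpha = alpha)$reject,
    iid_shuffle = {
      # deliberately invalid for autocorrelated data: shuffles within series
      set.seed(trial_seed_value)
      theta0 <- stat$fn(x, y)
      theta_surr <- vapply(seq_len(n_surrogates), function(i)
        as.numeric(stat$fn(x, sample(y))), numeric(1))
      surrogate_pvalue(theta0, theta_surr, stat$orientation) <= alpha
    },
    stop(sprintf("unknown test '%s'", test), call. = FALSE))
}

#' False-positive-rate experiment under the independence null
#'
#' Simulates `n_trials` pairs of independent series from a benchmark system
#' (two independent seeds per trial), applies the configured dependence test
#' to each pair, and reports the rejection fraction with a Wilson 95%
#' confidence interval. Trials whose test errors (e.g., a degenerate window)
#' are excluded and counted; more than 1% failed trials aborts the
#' experiment.
#'
#' @param system benchmark system id: one of `"ar1"`, `"logistic"`,
#'   `"sine_sawtooth"`, `"sine_threshold"`, `"coin"`, `"growth_collapse"`,
#'   `"fitzhugh_nagumo"`, `"lotka_volterra"`, `"random_walk"`,
#'   `"trended_ar1"`.
#' @param n series length per trial.
#' @param n_trials number of simulated pairs.
#' @param test `"tts"`, `"naive_tts"`, `"multi_lag_tts"`, `"detrend_tts"`,
#'   `"cyclic"`, `"block"`, `"iaaft"`, `"parametric"`, or `"iid_shuffle"`.
#' @param stat correlation statistic.
#' @param r truncation radius for the TTS family.
#' @param alpha significance level.
#' @param lag lag for the lag-l TTS test.
#' @param lags lag set for the multi-lag test.
#' @param master_seed master seed; per-trial seeds derive from it.
#' @param sys_params named list of extra generator parameters.
#' @param n_surrogates surrogate count for the surrogate-data comparators.
#' @param detrend_degree polynomial degree for `"detrend_tts"`.
#' @return object of class `rate_result` with `rate`, `n_trials`,
#'   `n_failed`, `ci_low`, `ci_high`, and the configuration.
#' @export
run_fpr_experiment <- function(system = "ar1", n = 500L, n_trials = 2000L,
                               test = "tts", stat = stat_pearson(), r = 19L,
                               alpha = 0.05, lag = 0L, lags = NULL,
                               master_seed = 1L, sys_params = list(),
                               n_surrogates = 99L, detrend_degree = NULL) {
  gen <- system_generator(system)
  rejects <- logical(n_trials)
  failed <- 0L
  for (i in seq_len(n_trials)) {
    s1 <- trial_seed(master_seed, 2L * i - 1L)
    s2 <- trial_seed(master_seed, 2L * i)
    out <- tryCatch({
      x <- gen(n, s1, sys_params)
      y <- gen(n, s2, sys_params)
      run_one_test(x, y, test, stat, r, alpha, lag, lags,
                   trial_seed_value = trial_seed(master_seed, 10000000L + i),
                   detrend_degree = detrend_degree, n_surrogates = n_surrogates)
    }, error = function(e) NA)
    if (is.na(out)) {
      failed <- failed + 1L
      if (failed > 0.01 * n_trials)
        stop(sprintf("more than 1%% of trials failed (system '%s', test '%s')",
                     system, test), call. = FALSE)
      rejects[i] <- NA
    } else rejects[i] <- out
  }
  summarize_rate(rejects, failed,
                 meta = list(kind = "fpr", system = system, test = test,
                             statistic = stat$name, n = n, r = r, alpha = alpha,
                             lag = lag, lags = lags, master_seed = master_seed))
}

#' Power experiment under a coupled alternative
#'
#' Simulates `n_trials` pairs from a coupled system (one seed per trial, the
#' two series share a trajectory) and reports the rejection fraction of the
#' configured test with a Wilson 95% confidence interval.
#'
#' @param system `"coupled_ar"` or `"coupled_logistic"`.
#' @inheritParams run_fpr_experiment
#' @return a `rate_result`.
#' @export
run_power_experiment <- function(system = "coupled_ar", n = 400L,
                                 n_trials = 2000L, test = "tts",
                                 stat = stat_pearson(), r = 19L, alpha = 0.05,
                                 lag = 0L, lags = NULL, master_seed = 1L,
                                 sys_params = list(), n_surrogates = 99L) {
  gen <- switch(system,
    coupled_ar = function(n, seed, p) do.call(simulate_coupled_ar,
                                              c(list(n = n, seed = seed), p)),
    coupled_logistic = function(n, seed, p) do.call(simulate_coupled_logistic,
                                                    c(list(n = n, seed = seed), p)),
    stop(sprintf("unknown coupled system '%s'", system), call. = FALSE))
  rejects <- logical(n_trials)
  failed <- 0L
  for (i in seq_len(n_trials)) {
    out <- tryCatch({
      pair <- gen(n, trial_seed(master_seed, i), sys_params)
      run_one_test(pair$x, pair$y, test, stat, r, alpha, lag, lags,
                   trial_seed_value = trial_seed(master_seed, 10000000L + i),
                   n_surrogates = n_surrogates)
    }, error = function(e) NA)
    if (is.na(out)) {
      failed <- failed + 1L
      if (failed > 0.01 * n_trials)
        stop("more than 1% of trials failed", call. = FALSE)
      rejects[i] <- NA
    } else rejects[i] <- out
  }
  summarize_rate(rejects, failed,
                 meta = list(kind = "power", system = system, test = test,
                             statistic = stat$name, n = n, r = r, alpha = alpha,
                             lag = lag, lags = lags, master_seed = master_seed))
}

summarize_rate <- function(rejects, failed, meta) {
  ok <- !is.na(rejects)
  k <- sum(rejects[ok])
  m <- sum(ok)
  ci <- wilson_ci(k, m)
  structure(c(list(rate = k / m, n_trials = m, n_failed = failed,
                   ci_low = unname(ci["low"]), ci_high = unname(ci["high"])),
              meta),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("%s experiment: system %s, test %s, statistic %s\n",
              toupper(x$kind), x$system, x$test, x$statistic))
  cat(sprintf("  rate = %.4f (95%% CI %.4f-%.4f) over %d trials (%d failed)\n",
              x$rate, x$ci_low, x$ci_high, x$n_trials, x$n_failed))
  invisible(x)
}

#' Run a benchmark grid from a configuration list
#'
#' Each cell of the grid names a system, a test, and a statistic; the
#' harness runs the corresponding experiment and returns one row per cell.
#' Deterministic under `master_seed`.
#'
#' @param config list (or path to a JSON file) with fields `kind`
#'   (`"fpr"`/`"power"`), `cells` (list of cell configs with `system`,
#'   `test`, `stat`, and optional overrides), and defaults `n`, `n_trials`,
#'   `r`, `alpha`, `master_seed`.
#' @return data.frame with one row per cell: system, test, statistic, alpha,
#'   r, lag, rate, ci_low, ci_high, n_trials, n_failed.
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  kind <- config$kind %||% "fpr"
  defaults <- list(n = config$n %||% 500L, n_trials = config$n_trials %||% 2000L,
                   r = config$r %||% 19L, alpha = config$alpha %||% 0.05,
                   master_seed = config$master_seed %||% 1L)
  rows <- lapply(config$cells, function(cell) {
    stat <- resolve_stat(cell$stat %||% "pearson", cell$stat_params %||% list())
    args <- list(system = cell$system,
                 n = cell$n %||% defaults$n,
                 n_trials = cell$n_trials %||% defaults$n_trials,
                 test = cell$test %||% "tts", stat = stat,
                 r = cell$r %||% defaults$r,
                 alpha = cell$alpha %||% defaults$alpha,
                 lag = cell$lag %||% 0L,
                 lags = if (!is.null(cell$lags)) as.integer(unlist(cell$lags)),
                 master_seed = cell$master_seed %||% defaults$master_seed,
                 sys_params = cell$sys_params %||% list())
    res <- if (kind == "power") do.call(run_power_experiment, args)
           else do.call(run_fpr_experiment, args)
    data.frame(system = res$system, test = res$test, statistic = res$statistic,
               alpha = res$alpha, r = res$r, lag = res$lag %||% NA_integer_,
               rate = res$rate, ci_low = res$ci_low, ci_high = res$ci_high,
               n_trials = res$n_trials, n_failed = res$n_failed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# statistic lookup by CLI/config name
resolve_stat <- function(name, params = list()) {
  switch(name,
    pearson = stat_pearson(),
    mi = stat_mi(k = params$k %||% 3L),
    mi_circular = stat_mi_circular(k = params$k %||% 3L),
    lsa = stat_local_similarity(D = params$D %||% 0L),
    ccm = stat_cross_map(E = params$E %||% 2L, tau = params$tau %||% 1L),
    `median-pearson` = stat_median_feature(stat_pearson()),
    stop(sprintf("unknown statistic '%s'", name), call. = FALSE))
}
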