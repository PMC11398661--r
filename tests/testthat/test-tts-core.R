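test_that("truncation and shifted windows follow the index formulas", {
  expect_identical(tts_truncate(1:4, 1), 2:3)
  expect_identical(tts_truncate(1:4, 0), 1:4)
  expect_identical(tts_truncate(1:5, 2), 3L)
  expect_error(tts_truncate(1:4, 2), "invalid radius")

  expect_identical(tts_shift(1:4, 1, 0), 2:3)
  expect_identical(tts_shift(1:4, 1, 1), 3:4)
  expect_identical(tts_shift(1:4, 1, -1), 1:2)
  expect_error(tts_shift(1:4, 1, 2), "invalid shift")

  m <- matrix(1:8, nrow = 2, dimnames = list(c("f1", "f2"), NULL))
  expect_identical(tts_truncate(m, 1), m[, 2:3])
})

test_that("lag pre-shift pairs the quoted index ranges and inverts on swap", {
  x <- 1:6; y <- 11:16
  p <- lag_preshift(x, y, 2)
  expect_identical(p$x, 3:6)
  expect_identical(p$y, 11:14)
  p <- lag_preshift(x, y, -2)
  expect_identical(p$x, 1:4)
  expect_identical(p$y, 13:16)
  p0 <- lag_preshift(x, y, 0)
  expect_identical(p0$x, x)
  expect_error(lag_preshift(x, y, 6), "invalid lag")

  # applying lag l to (x, y) and lag -l to the swapped pair selects the same
  # overlapping windows
  a <- lag_preshift(x, y, 3)
  b <- lag_preshift(y, x, -3)
  expect_identical(a$x, b$y)
  expect_identical(a$y, b$x)
})

test_that("B counting respects orientation and counts ties", {
  prof <- structure(list(r = 1L, shifts = -1:1, theta = c(0.1, 0.9, 0.2),
                         orientation = "higher_stronger", statistic = "pearson"),
                    class = "shift_profile")
  expect_equal(count_b(prof), 1)
  prof$theta <- c(0.5, 0.5, 0.5)
  expect_equal(count_b(prof), 3)
  prof$theta <- c(0.5, 0.2, 0.3)
  prof$orientation <- "lower_stronger"
  expect_equal(count_b(prof), 1)
})

test_that("u and naive statistics follow their defining formulas", {
  expect_equal(u_statistic(1, 19), 0.05)
  expect_equal(u_statistic(2, 38), 2 / 39)
  expect_equal(u_statistic(3, 1), 1.5)
  expect_equal(naive_p(1, 19), 1 / 39)
  expect_equal(naive_p(5, 2), 1)
  expect_error(u_statistic(0, 5), "B must be")
  expect_error(naive_p(12, 5), "B must be")
  # the naive rate inflation factor stays strictly below 2 at every radius
  r <- 1:10000
  ratio <- (2 * r + 1) / (r + 1)
  expect_true(all(ratio < 2))
  expect_true(all(abs(u_statistic(1, 5) / naive_p(1, 5) - 11 / 6) < 1e-15))
})

test_that("shift_profile matches a naive double loop and the fast path matches the generic loop", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(40:80, 1)
    r <- sample(1:5, 1)
    x <- as.numeric(arima.sim(list(ar = 0.5), n))
    y <- as.numeric(arima.sim(list(ar = 0.5), n))
    prof <- shift_profile(x, y, r, stat_pearson())
    ora <- oracle_shift_profile(x, y, r, function(a, b) abs(cor(a, b)))
    expect_equal(prof$theta, ora, tolerance = 1e-12)
    expect_equal(count_b(prof), oracle_count_b(prof$theta))
    # a statistic with the same value but a name that skips the fast path
    slow <- tts_stat("pearson_slow", function(a, b) abs(cor(a, b)))
    expect_equal(shift_profile(x, y, r, slow)$theta, prof$theta, tolerance = 1e-14)
  }
})

test_that("shift_profile reports the offending shift on a degenerate window", {
  x <- c(rep(1, 5), 2, rep(1, 6))  # constant in some windows
  y <- as.numeric(seq_len(12))
  expect_error(shift_profile(y, x, 3, stat_pearson()), "delta")
})

test_that("the self-pair gives a strict maximum at zero shift", {
  set.seed(11)
  x <- rnorm(100)
  res <- tts_test(x, x, r = 19)
  expect_equal(res$B, 1)
  expect_equal(res$u, 1 / 20)
  expect_true(res$reject)
  res7 <- tts_test(x, x, r = 7)
  expect_equal(res7$u, 1 / 8)
  expect_false(res7$reject)  # u = 0.125 > 0.05 despite the strict maximum
})

test_that("tts_test is deterministic and records its configuration", {
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.4), 150))
  y <- as.numeric(arima.sim(list(ar = 0.4), 150))
  a <- tts_test(x, y, r = 9, lag = 1, surrogate_from = "x")
  b <- tts_test(x, y, r = 9, lag = 1, surrogate_from = "x")
  expect_identical(a$u, b$u)
  expect_identical(a$profile$theta, b$profile$theta)
  expect_equal(a$surrogate_from, "x")
  expect_equal(a$lag, 1L)
  expect_equal(a$u, a$B / 10)
  expect_equal(a$p, min(a$u, 1))
})

test_that("a large radius relative to the series length warns", {
  set.seed(4)
  x <- rnorm(60); y <- rnorm(60)
  expect_warning(tts_test(x, y, r = 25), "third of the series length")
})

test_that("multi-lag test Bonferroni-corrects and reduces to the single test at m = 1", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.5), 200))
  y <- as.numeric(arima.sim(list(ar = 0.5), 200))
  single <- tts_test(x, y, r = 19, alpha = 0.05)
  multi1 <- multi_lag_tts(x, y, r = 19, lags = 0L, alpha = 0.05)
  expect_equal(multi1$reject, single$reject)
  expect_equal(multi1$per_lag[[1]]$u, single$u)

  multi5 <- multi_lag_tts(x, y, r = 39, lags = 0:4, alpha = 0.05)
  expect_equal(multi5$alpha / multi5$m, 0.01)
  us <- vapply(multi5$per_lag, function(z) z$u, 0)
  expect_equal(multi5$reject, any(us <= 0.01))
  expect_error(multi_lag_tts(x, y, r = 19, lags = c(0, 0)), "distinct")
})

test_that("optimal and default radii sit on the j*m/alpha - 1 lattice", {
  expect_equal(optimal_radius(0.05), 19L)
  expect_equal(optimal_radius(0.05, m = 5), 99L)
  expect_equal(optimal_radius(0.01, j = 2), 199L)
  expect_warning(r <- optimal_radius(0.07), "not an integer")
  expect_equal(r, round(1 / 0.07 - 1))
  expect_error(optimal_radius(0), "alpha")

  expect_equal(default_radius(400, 0.05), 79L)
  expect_equal(default_radius(100, 0.05), 19L)
  expect_error(default_radius(50, 0.05, m = 5), "length > 199")
})

test_that("detrend-retrend reduces to the plain test for a zero trend and reconstructs y at zero shift", {
  set.seed(6)
  x <- as.numeric(arima.sim(list(ar = 0.5), 120))
  y <- as.numeric(arima.sim(list(ar = 0.5), 120)) + 0.05 * (1:120)
  plain <- tts_test(x, y, r = 9)
  zero <- detrend_retrend_tts(x, y, r = 9, trend_fitter = function(v) rep(0, length(v)))
  expect_equal(zero$u, plain$u)
  expect_equal(zero$profile$theta, plain$profile$theta, tolerance = 1e-12)

  # zero-shift surrogate is exactly the truncated original: theta at delta=0
  # equals the plain unshifted correlation even after a polynomial detrend
  dtr <- detrend_retrend_tts(x, y, r = 9, trend_fitter = 1L)
  expect_equal(dtr$profile$theta[dtr$profile$shifts == 0],
               plain$profile$theta[plain$profile$shifts == 0], tolerance = 1e-10)
})

test_that("Benjamini-Hochberg adjustment clips superuniform values and steps up", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(1.4, 0.5)), c(1, 1))  # u > 1 clipped before adjustment
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  adj <- bh_adjust(runif(20))
  expect_true(all(diff(sort(adj)) >= -1e-15))
})

test_that("P(B = 1) is close to 1/(2r+1) for independent continuous inputs", {
  r <- 4
  hits <- vapply(1:1200, function(i) {
    x <- simulate_ar1(80, seed = trial_seed(77, 2 * i - 1))
    y <- simulate_ar1(80, seed = trial_seed(77, 2 * i))
    tts_test(x, y, r = r)$B == 1
  }, logical(1))
  p <- mean(hits)
  expected <- 1 / (2 * r + 1)
  se <- sqrt(expected * (1 - expected) / length(hits))
  expect_lt(abs(p - expected), 4 * se)
})
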