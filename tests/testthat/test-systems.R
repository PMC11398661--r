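test_that("generators are exactly reproducible under a fixed seed", {
  gens <- list(
    function(s) simulate_ar1(50, seed = s),
    function(s) simulate_logistic(50, seed = s),
    function(s) simulate_sine_sawtooth(50, seed = s),
    function(s) simulate_sine_threshold(50, seed = s),
    function(s) simulate_autocorrelated_coin(50, seed = s),
    function(s) simulate_growth_collapse(50, seed = s),
    function(s) simulate_random_walk(50, seed = s),
    function(s) unlist(simulate_coupled_ar(50, seed = s)),
    function(s) unlist(simulate_coupled_logistic(50, seed = s)))
  for (g in gens) {
    expect_identical(g(123L), g(123L))
    expect_false(identical(g(123L), g(124L)))
  }
})

test_that("AR(1) has the stationary variance and recovers an additive trend", {
  x <- simulate_ar1(1e5, phi = 0.5, sigma = 1, seed = 1)
  expect_lt(abs(var(x) - 1 / (1 - 0.25)) / (1 / 0.75), 0.05)
  # phi = 0 is iid Gaussian
  z <- simulate_ar1(1e4, phi = 0, sigma = 2, seed = 2)
  expect_lt(abs(sd(z) - 2), 0.1)
  expect_error(simulate_ar1(100, phi = 1.1), "stationary")
  # OLS detrending recovers the slope
  tr <- simulate_ar1(2000, phi = 0.5, trend_slope = 0.01, seed = 3)
  fit <- lm(tr ~ seq_along(tr))
  expect_lt(abs(coef(fit)[2] - 0.01), 3 * summary(fit)$coefficients[2, 2])
})

test_that("the logistic map follows its update rule and stays in [0, 1]", {
  x <- simulate_logistic(5, growth = 3.8, x0 = 0.4, burn_in = 0)
  expect_equal(x[2], 3.8 * 0.4 * 0.6)
  expect_equal(x[3], 3.8 * x[2] * (1 - x[2]))
  expect_identical(simulate_logistic(10, x0 = 0, burn_in = 0), rep(0, 10))
  long <- simulate_logistic(5000, seed = 4)
  expect_true(all(long >= 0 & long <= 1))
})

test_that("random-phase sine systems are mean-stationary and reduce when noise is off", {
  # marginal mean at a fixed time over realizations is 0 (random phase)
  at_t5 <- vapply(1:3000, function(i)
    simulate_sine_sawtooth(6, noise_sd = 0, seed = trial_seed(91, i))[5],
    numeric(1))
  expect_lt(abs(mean(at_t5)), 3 * sd(at_t5) / sqrt(3000))
  # zero noise reduces system iii to the pure sine
  s <- simulate_sine_sawtooth(100, noise_sd = 0, seed = 11)
  expect_true(all(abs(s) <= 1 + 1e-12))
  # threshold below the minimum leaves the sine unclipped
  set.seed(12); s1 <- simulate_sine_threshold(50, threshold = -2, noise_sd = 0)
  expect_true(all(abs(s1) <= 1 + 1e-12))
})

test_that("autocorrelated coin flips inherit the latent autocorrelation", {
  # constant q = 0.5, no noise: iid fair coin
  f <- simulate_autocorrelated_coin(1e4, q = 0.5, noise_sd = 0, seed = 13)
  expect_lt(abs(mean(f) - 0.5), 0.02)
  expect_identical(unique(simulate_autocorrelated_coin(100, q = 1, noise_sd = 0, seed = 1)), 1)
  g <- simulate_autocorrelated_coin(1e5, phi = 0.95, latent_sd = 1, noise_sd = 0, seed = 14)
  expect_gt(cor(g[-1], g[-length(g)]), 0.05)
})

test_that("growth-collapse orbits increase within a period and start at a random offset", {
  x <- simulate_growth_collapse(60, period = 20, seed = 15)
  # strictly increasing except at collapses
  drops <- which(diff(x) < 0)
  expect_true(all(diff(drops) == 20))
  offsets <- vapply(1:2000, function(i) {
    which.min(simulate_growth_collapse(20, period = 20, seed = trial_seed(92, i)))
  }, numeric(1))
  tab <- table(factor(offsets, levels = 1:20))
  expect_gt(chisq.test(tab)$p.value, 1e-4)  # uniform offset over the period
})

test_that("FitzHugh-Nagumo oscillates in the oscillatory regime and settles without input", {
  v <- simulate_fitzhugh_nagumo(2000, noise_sd = 0.02, burn_in = 2000, seed = 16)
  ac <- acf(v, lag.max = 500, plot = FALSE)$acf[-1]
  expect_gt(max(ac[100:500]), 0.3)  # a dominant period shows up in the ACF
  # fixed-point regime: zero input, zero noise
  v0 <- simulate_fitzhugh_nagumo(200, I = 0, noise_sd = 0, burn_in = 5000, seed = 17)
  expect_lt(var(v0), 1e-8)
  # independent seeds give independent noise streams
  a <- simulate_fitzhugh_nagumo(500, burn_in = 1000, seed = 18)
  b <- simulate_fitzhugh_nagumo(500, burn_in = 1000, seed = 19)
  expect_false(identical(a, b))
})

test_that("chaotic Lotka-Volterra abundances stay bounded and positive", {
  x <- simulate_lotka_volterra(10000, burn_in = 5000, seed = 20)
  expect_true(all(x > 0))
  expect_true(all(x < 2))
  expect_gt(sd(x), 0.01)  # not collapsed to a fixed point
  # decoupled: each species grows logistically to carrying capacity 1
  xd <- simulate_lotka_volterra(200, A = diag(4), burn_in = 2000, seed = 21)
  expect_lt(abs(mean(xd) - 1), 1e-6)
})

test_that("random walk increments are Gaussian and variance grows with time", {
  w <- simulate_random_walk(5000, sigma = 1.5, seed = 22)
  inc <- diff(w)
  expect_gt(shapiro.test(sample(inc, 500))$p.value, 1e-4)
  expect_lt(abs(sd(inc) - 1.5), 0.1)
  expect_identical(simulate_random_walk(10, sigma = 0, seed = 1), rep(0, 10))
  # Var(x_t) proportional to t
  at <- vapply(1:800, function(i) {
    w <- simulate_random_walk(400, seed = trial_seed(93, i))
    c(w[100], w[400])
  }, numeric(2))
  expect_gt(var(at[2, ]) / var(at[1, ]), 2.5)
})

test_that("coupled AR pair has its cross-correlation hill at minus the coupling lag", {
  peaks <- vapply(1:100, function(i) {
    pair <- simulate_coupled_ar(400, coupling_lag = 2, seed = trial_seed(94, i))
    prof <- shift_profile(pair$x, pair$y, 10, stat_pearson())
    prof$shifts[which.max(prof$theta)]
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(peaks)))), -2)
  expect_lt(abs(mean(peaks) + 2), 1)
  # synchronous coupling peaks at 0
  peaks0 <- vapply(1:50, function(i) {
    pair <- simulate_coupled_ar(400, coupling_lag = 0, seed = trial_seed(95, i))
    prof <- shift_profile(pair$x, pair$y, 6, stat_pearson())
    prof$shifts[which.max(prof$theta)]
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(peaks0)))), 0)
  # beta = 0: independent pair, near-zero cross-correlation at large n
  pair <- simulate_coupled_ar(20000, beta = 0, seed = 23)
  expect_lt(abs(cor(pair$x, pair$y)), 0.05)
})

test_that("coupled logistic maps stay in [0, 1] and decouple at zero coupling", {
  pair <- simulate_coupled_logistic(2000, seed = 24)
  expect_true(all(pair$x >= 0 & pair$x <= 1))
  expect_true(all(pair$y >= 0 & pair$y <= 1))
  dec <- simulate_coupled_logistic(500, beta_yx = 0, beta_xy = 0, seed = 25)
  # with no coupling y follows the plain logistic recursion
  expect_equal(dec$y[-1], 3.5 * dec$y[-500] * (1 - dec$y[-500]), tolerance = 1e-12)
  # strong unidirectional coupling is visible to cross-map skill
  skills <- vapply(1:30, function(i) {
    p <- simulate_coupled_logistic(400, beta_yx = 0.3, seed = trial_seed(96, i))
    cross_map_skill(p$x, p$y)
  }, numeric(1))
  expect_gt(mean(skills), 0.5)
})
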