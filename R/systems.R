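# Seeded generators for the benchmark dynamical systems used in the
# calibration (false positive rate) and power studies. Each generator is
# exactly reproducible under a fixed seed; independent pairs are produced by
# two calls with independent seeds and no shared state.

#' First-order autoregressive process
#'
#' `x_t = phi * x_{t-1} + e_t` with iid Gaussian noise, initialized from the
#' stationary marginal distribution so the whole series is stationary. A
#' nonzero `trend_slope` adds a deterministic linear trend `trend_slope * t`
#' on top of the stationary process (a trend-nonstationary benchmark).
#'
#' @param n series length.
#' @param phi autoregressive coefficient, `|phi| < 1`.
#' @param sigma innovation standard deviation.
#' @param trend_slope slope of the additive linear trend (default 0).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_ar1 <- function(n, phi = 0.5, sigma = 1, trend_slope = 0, seed = NULL) {
  if (abs(phi) >= 1) stop("|phi| must be < 1 for a stationary AR(1)", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  e <- stats::rnorm(n, 0, sigma)
  init <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
  x <- as.numeric(stats::filter(e, phi, method = "recursive", init = init))
  x + trend_slope * seq_len(n)
}

#' Logistic map
#'
#' `x_{t+1} = growth * x_t * (1 - x_t)`, a deterministic discrete-time model
#' of population growth with a carrying capacity; chaotic at the default
#' `growth = 3.8`. The initial condition is drawn uniformly (unless given)
#' and a burn-in is discarded so that samples start near the invariant
#' distribution.
#'
#' @param n series length.
#' @param growth growth parameter in (0, 4\].
#' @param x0 initial value in (0, 1); drawn uniformly when `NULL`.
#' @param burn_in iterations discarded before sampling.
#' @param seed optional integer seed (used to draw `x0`).
#' @return numeric vector of length `n`, all values in \[0, 1\].
#' @export
simulate_logistic <- function(n, growth = 3.8, x0 = NULL, burn_in = 100L,
                              seed = NULL) {
  if (growth <= 0 || growth > 4) stop("growth must be in (0, 4]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- stats::runif(1, 0.01, 0.99)
  if (x0 < 0 || x0 > 1) stop("x0 must be in [0, 1]", call. = FALSE)
  total <- n + burn_in
  x <- numeric(total)
  x[1] <- x0
  for (t in seq_len(total - 1L)) {
    x[t + 1L] <- growth * x[t] * (1 - x[t])
    if (is.na(x[t + 1L]) || x[t + 1L] < 0 || x[t + 1L] > 1)
      stop("logistic orbit escaped [0, 1]", call. = FALSE)
  }
  x[(burn_in + 1L):total]
}

#' Random-phase sine with sawtooth-modulated measurement noise
#'
#' A sine wave with a phase drawn uniformly on `[0, 2*pi)` (the random phase
#' is what makes the process stationary), plus Gaussian measurement noise
#' whose amplitude is modulated by a low-frequency random-phase sawtooth
#' wave. With `noise_sd = 0` this reduces to the pure random-phase sine.
#'
#' @param n series length.
#' @param period sine period in time steps.
#' @param noise_sd peak standard deviation of the measurement noise.
#' @param saw_period period of the modulating sawtooth.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_sine_sawtooth <- function(n, period = 20, noise_sd = 0.5,
                                   saw_period = 200, seed = NULL) {
  if (period < 2 || saw_period < 2) stop("periods must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n)
  phase <- stats::runif(1, 0, 2 * pi)
  saw_phase <- stats::runif(1, 0, 1)
  s <- sin(2 * pi * t / period + phase)
  saw <- (t / saw_period + saw_phase) %% 1
  s + stats::rnorm(n, 0, 1) * noise_sd * saw
}

#' Random-phase sine with a detection threshold and measurement noise
#'
#' A random-phase sine wave clipped from below at `threshold` (values below
#' the detection limit are reported at the limit) plus iid Gaussian
#' measurement noise. A threshold below -1 leaves the sine unclipped.
#'
#' @param n series length.
#' @param period sine period in time steps.
#' @param threshold detection threshold.
#' @param noise_sd measurement noise standard deviation.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_sine_threshold <- function(n, period = 20, threshold = -0.5,
                                    noise_sd = 0.25, seed = NULL) {
  if (period < 2) stop("period must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n)
  phase <- stats::runif(1, 0, 2 * pi)
  s <- pmax(sin(2 * pi * t / period + phase), threshold)
  s + stats::rnorm(n, 0, noise_sd)
}

#' Autocorrelated coin flips with measurement noise
#'
#' A latent stationary heads-probability process (the logistic transform of a
#' stationary AR(1)) drives Bernoulli flips coded 1/0, observed with additive
#' Gaussian measurement noise. The flips are autocorrelated because the
#' heads probability varies smoothly over time.
#'
#' @param n series length.
#' @param phi AR coefficient of the latent process.
#' @param latent_sd innovation standard deviation of the latent process.
#' @param noise_sd measurement noise standard deviation.
#' @param q constant heads probability overriding the latent process
#'   (`NULL`, the default, uses the latent AR(1)).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_autocorrelated_coin <- function(n, phi = 0.9, latent_sd = 0.5,
                                         noise_sd = 0.1, q = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qt <- if (is.null(q)) {
    a <- simulate_ar1(n, phi = phi, sigma = latent_sd)
    stats::plogis(a)
  } else {
    if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
    rep_len(q, n)
  }
  flips <- stats::rbinom(n, 1L, qt)
  flips + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
}

#' Exponential growth with periodic collapse and constant immigration
#'
#' A deterministic orbit in which a population grows exponentially, collapses
#' at the end of each period, and receives constant immigration, observed
#' from a uniformly random offset within one period (the random wait time is
#' what makes the observed process stationary). Within a period the series
#' is strictly increasing.
#'
#' @param n series length.
#' @param growth_rate per-step exponential growth rate (> 0).
#' @param period steps between collapses (>= 2).
#' @param immigration constant per-step immigration (>= 0).
#' @param seed optional integer seed (draws the random offset).
#' @return numeric vector of length `n`.
#' @export
simulate_growth_collapse <- function(n, growth_rate = 0.2, period = 20L,
                                     immigration = 1, seed = NULL) {
  if (growth_rate <= 0) stop("growth_rate must be positive", call. = FALSE)
  if (period < 2) stop("period must be >= 2", call. = FALSE)
  if (immigration < 0) stop("immigration must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  v <- numeric(period)
  v[1] <- immigration
  for (k in seq_len(period - 1L)) {
    v[k + 1L] <- v[k] * exp(growth_rate) + immigration
    if (!is.finite(v[k + 1L])) stop("growth overflow", call. = FALSE)
  }
  offset <- sample.int(period, 1L) - 1L
  v[(offset + seq_len(n) - 1L) %% period + 1L]
}

#' Stochastic FitzHugh-Nagumo oscillator
#'
#' Euler-Maruyama discretization of the two-variable neuronal model
#' `dv = (v - v^3/3 - w + I) dt + noise_sd dW`,
#' `dw = (v + a - b w) / tau dt`. The burn-in lets the system relax to its
#' attractor before sampling; the voltage-like variable `v` is returned.
#'
#' @param n series length.
#' @param a,b,tau,I model parameters (defaults in the oscillatory regime).
#' @param noise_sd process noise intensity on `v`.
#' @param dt integration step.
#' @param burn_in discarded initial steps (default 10000).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_fitzhugh_nagumo <- function(n, a = 0.7, b = 0.8, tau = 12.5, I = 0.5,
                                     noise_sd = 0.05, dt = 0.1,
                                     burn_in = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- n + burn_in
  v <- numeric(total); w <- numeric(total)
  v[1] <- 0; w[1] <- 0
  noise <- if (noise_sd > 0) stats::rnorm(total - 1L, 0, noise_sd * sqrt(dt)) else
    numeric(total - 1L)
  for (t in seq_len(total - 1L)) {
    v[t + 1L] <- v[t] + dt * (v[t] - v[t]^3 / 3 - w[t] + I) + noise[t]
    w[t + 1L] <- w[t] + dt * (v[t] + a - b * w[t]) / tau
    if (!is.finite(v[t + 1L]) || abs(v[t + 1L]) > 1e6)
      stop(sprintf("FitzHugh-Nagumo diverged (a=%g, b=%g, tau=%g, I=%g, dt=%g)",
                   a, b, tau, I, dt), call. = FALSE)
  }
  v[(burn_in + 1L):total]
}

#' Chaotic four-species competitive Lotka-Volterra model
#'
#' Discrete-time competitive Lotka-Volterra dynamics
#' `x_{t+1} = x_t + dt * x_t * r * (1 - A x_t)` with the classic
#' four-species chaotic parameterization. Initial abundances are drawn
#' uniformly; the burn-in is discarded and one designated species is
#' returned.
#'
#' @param n series length.
#' @param r intrinsic growth rates (length 4).
#' @param A 4-by-4 competition matrix (`NULL` uses the chaotic default).
#' @param dt integration step.
#' @param burn_in discarded initial steps (default 5000).
#' @param species which species' abundance to return (1-4).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_lotka_volterra <- function(n, r = c(1, 0.72, 1.53, 1.27), A = NULL,
                                    dt = 0.05, burn_in = 5000L, species = 1L,
                                    seed = NULL) {
  if (is.null(A)) {
    A <- matrix(c(1,    1.09, 1.52, 0,
                  0,    1,    0.44, 1.36,
                  2.33, 0,    1,    0.47,
                  1.21, 0.51, 0.35, 1), nrow = 4, byrow = TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  total <- n + burn_in
  out <- numeric(total)
  xs <- stats::runif(4, 0.1, 0.5)
  for (t in seq_len(total)) {
    out[t] <- xs[species]
    xs <- xs + dt * xs * r * (1 - as.numeric(A %*% xs))
    xs[xs < 0] <- 0
    if (all(xs == 0)) stop("all species went extinct", call. = FALSE)
    if (any(!is.finite(xs)) || any(xs > 1e6))
      stop("Lotka-Volterra diverged", call. = FALSE)
  }
  out[(burn_in + 1L):total]
}

#' Gaussian random walk
#'
#' Cumulative sum of iid Gaussian increments from 0; a nonstationary
#' benchmark.
#'
#' @param n series length.
#' @param sigma increment standard deviation (`0` gives a constant zero
#'   series).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_random_walk <- function(n, sigma = 1, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cumsum(stats::rnorm(n, 0, sigma))
}

#' Coupled linear autoregressive pair
#'
#' Two AR(1) processes with a lagged linear coupling, e.g. for
#' `direction = "y_to_x"`: `x_t = phi_x x_{t-1} + beta y_{t-lag} + e_t`,
#' `y_t = phi_y y_{t-1} + eta_t`. With `beta = 0` the pair is independent.
#' `direction = "both"` adds the symmetric term with the same lag.
#'
#' @param n series length.
#' @param phi_x,phi_y autoregressive coefficients (|.| < 1).
#' @param beta coupling strength.
#' @param coupling_lag lag at which the driver enters (default 2).
#' @param direction `"y_to_x"` (default), `"x_to_y"`, or `"both"`.
#' @param sigma innovation standard deviation.
#' @param burn_in discarded initial steps.
#' @param seed optional integer seed.
#' @return list with numeric vectors `x` and `y`.
#' @export
simulate_coupled_ar <- function(n, phi_x = 0.5, phi_y = 0.5, beta = 0.5,
                                coupling_lag = 2L, direction = c("y_to_x", "x_to_y", "both"),
                                sigma = 1, burn_in = 100L, seed = NULL) {
  direction <- match.arg(direction)
  if (abs(phi_x) >= 1 || abs(phi_y) >= 1)
    stop("|phi| must be < 1 for stationarity", call. = FALSE)
  if (direction == "both" && abs(phi_x) + abs(phi_y) + 2 * abs(beta) >= 2)
    stop("bidirectional coupling too strong for stationarity", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  total <- n + burn_in
  lag <- as.integer(coupling_lag)
  ex <- stats::rnorm(total, 0, sigma)
  ey <- stats::rnorm(total, 0, sigma)
  if (direction == "both") {
    x <- numeric(total); y <- numeric(total)
    for (t in seq_len(total)) {
      xl <- if (t > 1) x[t - 1] else 0
      yl <- if (t > 1) y[t - 1] else 0
      xd <- if (t > lag) x[t - lag] else 0
      yd <- if (t > lag) y[t - lag] else 0
      x[t] <- phi_x * xl + beta * yd + ex[t]
      y[t] <- phi_y * yl + beta * xd + ey[t]
    }
  } else {
    if (direction == "x_to_y") {
      # swap roles, then swap back
      res <- simulate_coupled_ar(n, phi_y, phi_x, beta, lag, "y_to_x",
                                 sigma, burn_in, seed = NULL)
      return(list(x = res$y, y = res$x))
    }
    init_y <- stats::rnorm(1, 0, sigma / sqrt(1 - phi_y^2))
    y <- as.numeric(stats::filter(ey, phi_y, method = "recursive", init = init_y))
    drv <- c(rep(0, lag), y[seq_len(total - lag)])
    x <- as.numeric(stats::filter(beta * drv + ex, phi_x, method = "recursive"))
  }
  keep <- (burn_in + 1L):total
  list(x = x[keep], y = y[keep])
}

#' Coupled logistic map pair
#'
#' Competition-inspired nonlinear maps
#' `x_{t+1} = x_t (r_x - r_x x_t - beta_yx y_{t-lag})` and symmetrically for
#' `y`. The defaults give a chaotic pair in which `y` influences `x`
#' unidirectionally. Initial conditions are uniform; a short burn-in is
#' discarded.
#'
#' @param n series length.
#' @param r_x,r_y growth parameters.
#' @param beta_xy coupling of `x` into `y` (default 0: unidirectional).
#' @param beta_yx coupling of `y` into `x`.
#' @param lag coupling lag in steps.
#' @param burn_in discarded initial steps.
#' @param seed optional integer seed.
#' @return list with numeric vectors `x` and `y`, all values in \[0, 1\].
#' @export
simulate_coupled_logistic <- function(n, r_x = 3.8, r_y = 3.5, beta_xy = 0,
                                      beta_yx = 0.1, lag = 2L, burn_in = 300L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lag <- max(1L, as.integer(lag))
  total <- n + burn_in + lag
  x <- numeric(total); y <- numeric(total)
  x[seq_len(lag)] <- stats::runif(lag, 0.2, 0.8)
  y[seq_len(lag)] <- stats::runif(lag, 0.2, 0.8)
  for (t in lag:(total - 1L)) {
    x[t + 1L] <- x[t] * (r_x - r_x * x[t] - beta_yx * y[t - lag + 1L])
    y[t + 1L] <- y[t] * (r_y - r_y * y[t] - beta_xy * x[t - lag + 1L])
    if (any(!is.finite(c(x[t + 1L], y[t + 1L]))) ||
        x[t + 1L] < 0 || x[t + 1L] > 1 || y[t + 1L] < 0 || y[t + 1L] > 1)
      stop("coupled logistic orbit escaped [0, 1]", call. = FALSE)
  }
  keep <- (burn_in + lag + 1L):total
  list(x = x[keep], y = y[keep])
}
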