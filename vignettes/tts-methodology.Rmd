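---
title: "The truncated time-shift test: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The truncated time-shift test: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttstest)
```

## The problem and the procedure

Two autocorrelated series can look strongly correlated while being
statistically independent: smooth trajectories wander together by chance, and
shuffling-based permutation tests, which destroy the autocorrelation in their
null ensemble, reject far too often. The truncated time-shift (TTS) test
replaces shuffles with *time shifts*. With truncation radius $r$, the central
window of $x$ is correlated against the $2r+1$ windows of $y$ at shifts
$\delta = -r,\dots,r$; $B$ counts the shifts whose correlation is at least as
strong as the unshifted one, and the decision statistic is

$$u = \frac{B}{r+1}.$$

Under the null hypothesis that the two series are independent, and assuming
that the *shifted* series is strict-sense stationary, $u$ is superuniform:
$P(u \le \alpha) \le \alpha$. Nothing is assumed about the other series, the
marginal distributions, or the correlation statistic, which is what makes the
test usable with nonlinear statistics (mutual information, cross-map skill,
local similarity) for which no parametric null exists. The cost of this
generality is conservatism: $u$ only takes values on a grid of width
$1/(r+1)$, and the naive proportion $B/(2r+1)$ — which is *not* a valid
p-value because neighbouring shifted windows are strongly dependent — is
smaller than $u$ by a factor approaching 2.

## Parameters that matter

**Truncation radius `r`** (time steps). Controls both the number of
surrogates ($2r$) and the data discarded ($2r$ points). Because rejection at
level $\alpha$ requires $B \le \alpha(r+1)$, only radii of the form
$r = jm/\alpha - 1$ (a positive integer $j$, $m$ lags tested) buy extra power;
intermediate radii demand the same $B$ from less data. `optimal_radius()`
returns this lattice ($r = 19$ for one test at $\alpha = 0.05$; $r = 99$ for
five lags); `default_radius()` additionally caps the radius at a fifth of the
series length, since small radii empirically win for short series. `tts_test`
warns when $r$ exceeds a third of the (lag-adjusted) length, because the test
then probes dependence with only a short central window of $x$.

**Lag `lag` / `lags`**. A hypothesized coupling delay is aligned before
testing by pairing $\{x_{1+l},\dots,x_n\}$ with $\{y_1,\dots,y_{n-l}\}$. The
lag must come from mechanism or independent pilot data: choosing it by
scanning the tested series guarantees rejection, so the package deliberately
offers no lag-scanning mode. When the lag is only known to lie in a set of
$m$ candidates, `multi_lag_tts()` tests each at level $\alpha/m$; the
Bonferroni correction preserves validity exactly.

**`surrogate_from`**. Validity requires stationarity of the shifted series
only. By default surrogates are generated from `y`; pass
`surrogate_from = "x"` when `x` is the series you are willing to assume
stationary.

**The statistic**. Any `tts_stat` works. Statistics where *smaller* is
stronger (error-like statistics such as a prediction MSE) carry
`orientation = "lower_stronger"`; the engine inverts the counting comparison
rather than negating values, so reported correlation profiles remain on their
natural scale. Ties in the comparison are counted into $B$ (exact `>=`/`<=`,
no tolerance), which can only make the test more conservative.

## Statistics shipped

* **Pearson strength**: $|\hat\rho|$; degenerate (zero-variance) windows
  raise an error naming the offending shift rather than returning 0.
* **kNN mutual information**: the Kraskov $I^{(1)}$ estimator with $k = 3$
  neighbours by default, strict inequality in the marginal counts, and the
  joint-space metric taken as the maximum of the two marginal distances. A
  circular (angular, $\arccos\cos(\alpha-\beta)$) marginal metric supports
  direction-of-motion variables; `sin_mod_transform()` ($|\sin\varphi|$)
  offers a linearizing alternative.
* **Local similarity**: maximal absolute partial sum of products of
  normal-score-transformed series over contiguous intervals and delays
  $|d| \le D$, divided by $n$. The delay bound defaults to $D = 0$ and is
  exposed; ranks are averaged across ties before the Gaussian quantile map.
* **Cross-map skill**: delay-embeds the predictor ($E = 2$, $\tau = 1$ by
  default), predicts the target from the $E+1$ nearest embedded neighbours
  with $e^{-d_i/d_1}$ weights (indicator weights when $d_1 = 0$; the full
  set of embedded points serves as the library), and correlates predictions
  with observations. Neighbour ties break by lowest index.
* **Median over shared features**: for feature-by-time tables (e.g. OTU
  relative abundances at two body sites), the base statistic per shared
  feature ID, aggregated by the median — the "typical feature" correlation —
  with the even-count median taken as the mean of the two central order
  statistics. `gap_fill()` (linear interpolation or seeded resampling)
  handles missing interior samples; testing refuses series with remaining
  gaps.

## Comparators

`surrogate_test()` implements the classical surrogate-data recipe
($p = (N_{\ge}+1)/(N+1)$, 499 surrogates by default) with three generators:
cyclic permutations (all $n-1$ rotations, deterministic), the stationary
block bootstrap (geometric blocks, restart probability $p = 0.05$, mean block
length $\approx 20$, wrap-around continuation), and IAAFT (a fixed 200
iterations, no early exit; `"true_spectrum"` output by default). All three
are preceded by circularization: both series are cut to the index range
$(k_1, k_2)$ minimizing $\sum_{i=0}^{L}(y_{k_2+i}-y_{k_1+i})^2$ with $L = 10$
and the cut points confined to within 40 positions of the ends, mismatch
evaluated on the surrogate-source series, lexicographic tie-break. These
tests can be miscalibrated off their validity conditions — that is precisely
what the benchmark harness demonstrates — and are included as comparators,
not recommendations.

`corrected_pearson_test()` is the parametric comparator: the variance of the
sample correlation under independence is estimated as
$\hat\sigma^2_\rho = \sum_k n_k \hat C_x(k)\hat C_y(k) / (n^2
\hat\sigma^2_x\hat\sigma^2_y)$, converted to an effective sample size
$\hat m = 1 + 1/\hat\sigma^2_\rho$ and a $t$ statistic with $\hat m - 2$
degrees of freedom. Numerical choices: non-integer degrees of freedom are
passed to the continuous $t$ distribution (rounding would change p-values); a
nonpositive variance estimate falls back to $1/n$ — the exact
no-autocorrelation value — and is flagged; the `"quarter_truncated"` variant
zeroes autocovariance products strictly above lag $n/4$; $\hat m \le 2$
yields $p = 1$ with a warning rather than an undefined test.

## Detrending and retrending

For series that are stationary around a deterministic trend,
`detrend_retrend_tts()` (1) fits a trend to the surrogate-source series
(ordinary least-squares polynomial, degree 1 by default — the trend family is
a user choice, and any function returning an equal-length trend is accepted);
(2) shifts the residual; (3) adds the truncated trend back to every shifted
window. The zero-shift surrogate reconstructs the original truncated series
exactly, so the statistic at $\delta = 0$ is unchanged and a zero trend
reduces the procedure to the plain test.

## The synthetic benchmark systems

The generators in `simulate_*` emulate the qualitative behaviour of standard
calibration benchmarks: a stationary AR(1) (coefficient 0.5, unit Gaussian
innovations, stationary initialization), the chaotic logistic map (growth
3.8, uniform initial condition, 100-step burn-in toward the invariant
measure), random-phase sines with sawtooth-modulated or thresholded
measurement noise (the random phase is what makes these stationary),
autocorrelated coin flips (a logistic-AR(1) latent heads probability),
exponential growth with periodic collapse observed from a uniformly random
offset, a stochastic FitzHugh–Nagumo oscillator (Euler–Maruyama, $10^4$-step
burn-in) and a chaotic four-species competitive Lotka–Volterra model
($5\times10^3$-step burn-in) as biologically inspired nonlinear systems, plus
two nonstationary controls (a Gaussian random walk and the AR(1) with an
additive linear trend). Coupled alternatives are a lag-2 linear AR pair
($x_t = 0.5x_{t-1} + 0.5\,y_{t-2} + \varepsilon_t$) and a unidirectionally
coupled logistic-map pair with competition-style coupling. Where a published
parameterization was not printed alongside the qualitative descriptions,
defaults were fixed once at values a practitioner would call typical (AR
coefficient 0.5, logistic growth 3.8, coupling 0.5 at lag 2) and are fully
exposed as arguments.

What the generators do *not* emulate: observational irregular sampling,
heavy-tailed measurement error, slowly varying parameters, multiple coupling
lags, and compositional constraints of relative-abundance data. A calibrated
test on these benchmarks therefore demonstrates correctness of the machinery
under the stated stationarity conditions, not robustness to every real-data
pathology; on genuinely nonstationary inputs the TTS guarantee simply does
not apply (the trended systems are included to show exactly that, and the
detrend–retrend variant addresses the deterministic-trend case).

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed; experiment grids derive one
seed per trial from a master seed by a fixed affine map modulo $2^{31}-1$, so
benchmark tables are bit-for-bit reproducible. The simulation studies in the
test suite use 2000 trials per cell for the headline calibration and validity
checks (binomial standard error $\approx 0.5$ percentage points at the 5%
level, with all assertions allowing three standard errors), series length 500
for null calibration and 400 for the lagged-power study, and 100–400 trials
for secondary Monte Carlo checks; these sizes were chosen as the smallest
grids whose margins still make the assertions meaningful.

## Known limitations

* Power is modest by construction: with $r = 19$ at $\alpha = 0.05$,
  rejection requires the unshifted correlation to beat all 38 shifted ones.
* Phase-synchronized periodic pairs can defeat the test entirely (every shift
  of a common period produces an equally strong correlation), a pathology
  shared by any deterministic test under the same assumptions.
* The test is for *unconditional* dependence; it is not a Granger-causality
  or conditional-independence test, and no such extension is attempted here.
* Lags must be few and externally motivated; a wide lag scan costs power
  through the Bonferroni factor and radius requirement ($r \ge m/\alpha - 1$
  needs a series longer than $2(m/\alpha - 1)$).
* Stationarity itself is an assumption, not something the package certifies:
  no stationarity pre-test is included, because a finite series is compatible
  with both stationary and nonstationary models.
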