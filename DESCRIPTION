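Package: ttstest
Title: Truncated Time-Shift Tests for Dependence Between Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonparametric tests for statistical dependence between a pair of
    regularly sampled time series. The central method is the truncated
    time-shift (TTS) test, a surrogate-data procedure whose false positive
    rate is controlled whenever at least one of the two series is strict-sense
    stationary, and which accepts any correlation statistic. The package
    ships a suite of pluggable statistics (Pearson correlation strength,
    k-nearest-neighbour mutual information with Euclidean or circular
    metrics, local similarity, cross-map skill, median over shared features),
    comparator surrogate procedures (cyclic permutation, stationary block
    bootstrap, iterative amplitude-adjusted Fourier transform) with
    circularization preprocessing, an autocovariance-corrected parametric
    Pearson test, seeded generators for benchmark dynamical systems, and a
    simulation harness for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
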