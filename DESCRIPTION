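Package: scedcp
Title: Bayesian Unknown Change-Point and Simulation Modeling Analysis for
    Single-Case Experimental Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyzes two-phase single-case experimental design (SCED) time
    series with a Bayesian unknown change-point (BUCP) model and with
    Simulation Modeling Analysis (SMA). The BUCP model is an interrupted
    time series with a piecewise-constant level, lag-1 autocorrelated
    errors, and a discrete latent change point, fitted by a
    Metropolis-within-Gibbs sampler with an exact categorical update for
    the change point. Posterior draws feed highest-density intervals,
    autocorrelation-aware standardized mean-difference effect sizes,
    region-of-practical-equivalence (ROPE) decisions, and an
    immediacy/latency classification of the intervention effect. SMA tests
    level and slope change by comparing an observed phase-contrast
    correlation against autocorrelation-matched Gaussian surrogates. A
    synthetic-data generator produces two-phase AR(1) series with known
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
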