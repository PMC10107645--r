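Package: mplcox
Title: Penalised Likelihood Extended Cox Models for Partly Interval-Censored Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the extended Cox proportional hazards model with
    time-varying covariates to partly interval-censored survival data by
    maximum penalised likelihood. The baseline hazard is approximated by a
    non-negative cubic M-spline basis and estimated subject to
    non-negativity constraints with an alternating Newton /
    multiplicative-iterative algorithm; the smoothing parameter is selected
    automatically by an approximate marginal likelihood; constrained
    sandwich covariances provide standard errors, Wald tests and
    delta-method confidence intervals for predicted survival curves.
    Includes data generators for simulation experiments with right-, left-
    and interval-censored observations and piecewise-constant or continuous
    time-varying covariates, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    splines,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
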