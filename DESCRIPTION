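Package: smokelag
Title: Exposure-Lag-Response Modelling of Smoking Prevalence and Lung
    Cancer Incidence
Version: 0.1.0
Authors@R:
    person("smokelag", "developers", email = "smokelag@example.org",
           role = c("aut", "cre"))
Description: Distributed lag non-linear models (DLNM) for the delayed effect
    of population smoking prevalence on lung cancer incidence in registry
    data. Builds natural-spline exposure-lag cross-bases with a lag-0
    constraint, fits negative binomial generalized linear models with a
    population offset by full maximum likelihood, corrects the covariance
    with a registry-clustered sandwich estimator, and predicts
    backward-perspective incidence rate ratio (IRR) surfaces, cumulative
    IRRs with delta-method intervals, and "what-if" prevalence scenarios.
    Includes a registry-structured synthetic data generator, simulation-based
    scaled quantile residual diagnostics, and a configured pipeline with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    numDeriv,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
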