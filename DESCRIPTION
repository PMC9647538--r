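Package: psytraj
Title: Latent Trajectory Classes of Long-Term Psychotic Symptom Course
Version: 0.1.0
Authors@R:
    person("AESOP", "Reanalysis Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the long-term course of psychotic disorders
    from month-by-month symptom timelines. Aggregates monthly presence/absence
    ratings into months-psychotic-per-year series, fits growth mixture models
    (finite mixtures of Gaussian latent growth curves, with or without random
    intercepts and slopes) by EM under a missing-at-random full-information
    likelihood, and runs a model-selection ladder over class counts and
    polynomial degrees using BIC, entropy, the Lo-Mendell-Rubin test and a
    parametric bootstrapped likelihood ratio test. Also provides the classical
    episodic/continuous/neither course typology and a symptomatic recovery
    rule, trajectory-by-outcome cross-tabulations, logistic-regression
    associations between baseline covariates and trajectory class, a
    random-intercept logistic check of the missing-at-random assumption, and a
    calibrated synthetic cohort generator so that the whole pipeline is
    testable without access to individual-level patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
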