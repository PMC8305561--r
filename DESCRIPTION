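Package: prepost
Title: Analysis of Two-Arm Randomized Pre-Post Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for the treatment effect in two-arm
    randomized trials with one baseline and one post-treatment measurement.
    Implements the six standard analyses (ANOVA on the post score, ANCOVA
    with and without a baseline-by-treatment interaction, ANOVA on the
    change score, repeated-measures and constrained repeated-measures GLS
    models fitted by REML) together with model-based, heteroscedasticity-
    consistent (HC0-HC3), adjusted-HC, bootstrap and REML plug-in standard
    errors.  Provides closed-form true variances of every estimator under
    homogeneous and heterogeneous bivariate-normal populations, efficiency
    deltas, a scenario-preset trial simulator, and a Monte Carlo engine for
    bias, variance, coverage and type-I-error experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    nlme,
    withr,
    jsonlite
Config/testthat/edition: 3
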