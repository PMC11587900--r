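Package: obsmed
Title: Oxidative Balance Score, Survey-Weighted Regression, and Mediation
    Analysis for Complex-Survey Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how oxidative balance relates to
    cardiovascular disease in complex-survey cohorts such as NHANES.
    Implements construction of the 20-component oxidative balance score
    (OBS) with gender-specific tertiles and pro-/antioxidant
    directionality, survey-weighted logistic regression with
    Taylor-linearized (design-based) variance estimation over
    stratum/PSU clusters, design-adjusted (Rao-Scott) chi-square tests,
    restricted-cubic-spline modelling with nonlinearity tests and
    inflection-point detection, product-of-coefficients mediation with
    the distribution-of-product confidence interval, multiple imputation
    by chained equations with Rubin pooling, and a synthetic cohort
    generator with a known mediation structure for validation. An
    orchestration layer runs the full analysis from a configuration file
    and emits a reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
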