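Package: thermonorm
Title: Reaction-Norm Genetic Analysis of Heat Tolerance from Weather and
    Carcass Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds lifetime heat-load covariates (temperature, relative
    humidity and the temperature-humidity index averaged over age windows)
    from hourly weather series, screens them against carcass traits with
    fixed-effect Legendre regressions ranked by R-squared and BIC, fits a
    Bayesian random-regression (reaction-norm) sire model with a single-step
    genomic relationship kernel, correlated intercept and slope sire effects,
    batch and litter effects and decile-defined heterogeneous residual
    variances by Gibbs sampling, and derives heritability trajectories,
    environment-by-environment genetic correlations, reaction norms and
    tolerance-based sire rankings. Includes a calibrated synthetic-data
    generator so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
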