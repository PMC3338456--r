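Package: meadowsem
Title: Hierarchical Bayesian Structural Equation Models for Grazing,
    Meadow Wetness and Amphibian Occupancy
Version: 0.1.0
Authors@R: person("Meadow", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing drivers of amphibian occupancy in grazed
    montane meadows. Provides a seeded synthetic-data generator emulating a
    multi-allotment meadow monitoring design, composite meadow-scale
    hydrologic ranking, exploratory bivariate regressions (fractional
    logistic regression for proportion responses, linear and quadratic fits
    with Box-Cox remediation and AIC selection), a hierarchical Bayesian
    structural equation model with a latent forage-quality factor fitted by
    Metropolis-within-Gibbs MCMC, convergence and model-comparison
    diagnostics (Gelman-Rubin R-hat, DIC), and leave-one-out ROC/AUC
    validation of occupancy predictions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
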