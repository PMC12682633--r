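Package: bapcburden
Title: Bayesian Age-Period-Cohort Modelling of Disease Burden
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for descriptive and projective analysis of disease burden
    on age-by-period (Lexis) grids: reading and writing long-format burden
    tables in the GBD results dialect, age-standardized rates with pluggable
    standard populations, estimated annual percentage change (EAPC) trends,
    population-attributable-fraction risk attribution, and a Bayesian
    age-period-cohort model with random-walk smoothing priors, penalized
    complexity priors on the smoothing standard deviations, optional
    log-linear exposure covariates, Laplace-approximate inference with
    hyperparameter integration, random-walk extrapolation forecasts with
    Monte Carlo uncertainty, and a back-testing harness (MAE, RMSE, CRPS,
    interval coverage, DIC, WAIC, CPO). A synthetic-data generator with
    known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    withr,
    optparse
Config/testthat/edition: 3
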