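Package: pocure
Title: Cure-Fraction Survival Analysis with Jackknife Pseudo-Observations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Regression modelling of survival data with a cured fraction
    using jackknife pseudo-observations.  Nonparametric estimators of the
    uncured rate and of the susceptible distribution (Kaplan-Meier and
    Tsodikov-type) are turned into leave-one-out pseudo-observations and
    fitted by generalized estimating equations, giving direct estimates of
    the incidence and latency components of the mixture cure model and of
    the long- and short-term effects of the bounded-cumulative-hazard
    (promotion time) model.  Includes SCAD-penalized estimating equations
    with cross-validated tuning for variable selection, jackknife and
    sandwich variance estimators, pseudo-residual diagnostics, and
    calibrated simulators for Monte Carlo study of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), survival, jsonlite, optparse, withr
Config/testthat/edition: 3
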