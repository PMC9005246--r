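Package: heatlag
Title: Two-Stage Modelling of Heat-Attributable Mortality from Climate
    Oscillation Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates annual summer heat-attributable fractions of
    all-cause mortality from daily temperature and death-count series
    with a time-varying distributed lag nonlinear model (quasi-Poisson
    regression on a temperature-by-lag cross-basis), and predicts those
    fractions from monthly climate teleconnection index curves (AMO,
    SOI, AO, NAO, ONI, PDO, PNA) with a scalar-on-function linear model
    estimated by component-wise gradient boosting over penalized spline
    base learners.  Includes a synthetic-data generator with known
    exposure-lag-response ground truth so both stages can be validated
    end to end, empirical confidence intervals by coefficient
    simulation, and repeated cross-validated R-squared evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
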