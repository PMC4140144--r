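Package: bloodrc
Title: Multivariate Blood-Based Estimation of Hematopoietic Radiation Injury Response Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and validating multivariate linear scoring
    algorithms that estimate the METREPOL hematopoietic acute radiation
    syndrome response category 3 (RC3) from serial complete blood counts and
    serum chemistry in a nonhuman-primate total-body irradiation model.
    Provides a longitudinal synthetic blood-panel cohort generator driven by
    published radioresponse kinetics, precision and radioresponsiveness
    screening filters, correlation-based collinearity downselection, ordinary
    and stepwise least-squares model fitting with a residual-diagnostics
    acceptance gate (Durbin-Watson, Shapiro-Wilk, Breusch-Pagan, eigenvalue
    criterion, variance inflation factors), RC3 estimation with confidence and
    prediction interval widths and band-assignment accuracy scoring, and
    univariate and biomarker-panel ROC analysis with bootstrap confidence
    limits. The two published RC3 scoring algorithms ("CBC" and "CBC-SCHEM")
    and the per-animal reference estimates are packaged as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    lmtest,
    pROC,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
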