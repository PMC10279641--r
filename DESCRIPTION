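Package: qpipe
Title: Quasi-Pipe Model Allometry for Tree Leaf Area, Leaf Mass and Stand LAI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating tree leaf area and leaf dry mass from
    ground-measurable stem dimensions using the quasi-pipe (qPipe) allometry,
    in which the stem cross-sectional area at the crown base is approximated
    from breast-height area and crown ratio under a paraboloid stem-taper
    assumption. Provides standardized major axis (Model II) regression with
    common-slope likelihood-ratio tests, Sidak-corrected elevation
    comparisons and a robust variant; Model I prediction via ordinary least
    squares and species random-intercept mixed models with AIC selection,
    log-transform bias correction and 95% prediction intervals; iterative
    Grubbs outlier filtering; stem-taper error diagnostics; stand-level leaf
    area index and leaf biomass estimation with propagated intervals; a
    registry of published global allometric coefficients; a seeded synthetic
    forest generator; and inventory file readers with configurable column
    maps plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
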