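Package: cropshift
Title: Hierarchical Bayesian Crop-Yield Modelling and Profit-Maximizing
    Land Reallocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying crop reallocation as an adaptation to a
    changing climate. Fits a three-level Bayesian panel model of county
    log-yields with weather predictors (trend, crop water deficit index,
    growing and extreme degree-days) and covariate-driven partial pooling
    of county coefficients, so that yield responses can be predicted even
    in counties never observed growing a crop. Includes single-sine
    degree-day computation, four ordinary least-squares baseline
    specifications with a temporal cross-validation harness, a
    profit-maximizing land-reallocation linear program with hidden-cost
    calibration, posterior-draw Monte Carlo optimization and
    switching-cost sweeps, and a synthetic county-panel generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    boot,
    coda,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
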