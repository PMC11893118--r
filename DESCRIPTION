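Package: cropclock
Title: Agro-Meteorological Derivation and Statistical Modelling of Green
    Bean Phenology and Fresh Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives phenology-anchored agro-meteorological variables
    (thermal time as growing degree days with base/cap truncation, stress
    days above temperature thresholds, windowed radiation, temperature and
    vapour-pressure statistics) from daily weather series matched to
    commercial crop records, and fits the statistical models used to
    predict green bean growth durations and fresh pod yield:
    season-grouped three-parameter logistic growth curves of fresh pod
    weight against thermal time, backward stepwise-AIC linear duration
    models with 80 percent prediction intervals, yield-component
    estimation with delta-method error propagation and sample-size rules,
    photothermal productivity indices, and multi-year sowing-date
    percentile scans. Includes a deterministic synthetic weather generator
    emulating subtropical Queensland seasonality so every analysis runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
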