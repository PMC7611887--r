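Package: airshift
Title: Mobility-Coupled Urban Air-Quality Anomalies and Health Impacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how large-scale changes in urban mobility
    affect ambient air quality and population health. Provides baseline
    re-normalisation of provider mobility indices, aggregation of monitoring
    station data to city-level pollutant series, weather-corrected
    counterfactual prediction of NO2 and PM2.5 concentrations with linear and
    gradient-boosted regression models, moving-block bootstrap confidence
    intervals for annual anomalies, Spearman rank correlation between weekly
    mobility and pollution changes, and attributable-fraction health impact
    assessment from concentration-response coefficients. Includes a synthetic
    city-data generator with known ground truth so the full pipeline can be
    exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
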