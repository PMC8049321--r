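Package: whalephen
Title: Migration Phenology, Abundance Trends, and Entanglement Risk from
    Whale Sighting Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long-term daily counts of baleen whales
    from a fixed observation point: reconstruction of observation effort
    from weather records with classification trees and removal of
    false-zero days, negative-binomial trend models of weekly counts with
    effort offsets, percentile-based estimates of arrival, peak, and
    departure timing, environmental covariate construction (front
    intensity index, upwelling index, spring transition from Ekman
    transport, lagged basin-scale climate indices), hierarchy-preserving
    backward-stepwise attribution of timing to environmental drivers with
    forecast and year-removal validation, and linear models relating
    monthly entanglement counts to whale abundance and migration timing.
    Includes a seeded synthetic-data generator that reproduces the
    statistical structure of such monitoring series for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
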