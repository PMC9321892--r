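Package: pairforage
Title: Spatio-Temporal Coordination Analysis for Provisioning Parent Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify spatio-temporal coordination of biparental
    provisioning from automated radio-tracking arrays. Simulates central-place
    foraging pairs under alternative coordination scenarios, multilaterates
    tag positions from received signal strength (RSSI) logs, estimates
    dynamic Brownian bridge utilization distributions (UDs) per time window,
    compares male and female UDs with the earth mover's distance (EMD) across
    signed time lags, and fits weighted crossed-random-effects mixed models
    to the resulting lag correlograms. Includes secondary analyses of
    foraging angles (circular correlation), pair proximity by distance from
    the nest, and the relation between space-use similarity and provisioning
    rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    lme4,
    pbkrtest,
    emmeans,
    stats,
    utils,
    readr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
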