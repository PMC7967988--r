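Package: migratimer
Title: Departure and Arrival Timing of GPS-Tracked Migratory Shorebirds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the timing of migration in GPS-tagged
    shorebirds wintering at a fixed site. Detects departure and arrival
    events from raw fix tables, classifies wintering, stop-over and
    breeding residencies, computes flight-track metrics (great-circle and
    flown distances, track curvature, corridor means), derives
    daylight-window weather predictors with circular wind statistics and a
    global-radiation cloudiness proxy, computes the tailwind component of
    wind support, screens a large predictor set with cross-validated LASSO
    followed by confirmatory mixed models with an individual random
    intercept, and quantifies intra-individual repeatability of migration
    timing across years. Includes a synthetic track-and-weather generator
    with known ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    geosphere,
    glmmTMB,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
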