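Package: gilashift
Title: Dispersal-Constrained Habitat Forecasting for Gila Monsters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for presence-only ensemble habitat
    modeling with bias-corrected pseudo-absences, Brownian bridge movement
    models fit to telemetry, decadal climate projection with a
    dispersal-limited occupiable-habitat update, and protected-area gap
    tabulation. Includes a synthetic-landscape generator so every stage is
    testable without sensitive occurrence data: Gila monster localities are
    withheld from public release, so the pipeline is exercised on simulated
    landscapes with known truth. Rasters use the plain-text ESRI ASCII grid
    format; polygons use GeoJSON; all tabular interfaces are tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    sp,
    mgcv,
    glmnet,
    randomForest,
    xgboost,
    lme4,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
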