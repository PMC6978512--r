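Package: deadwood
Title: Standing-Dead Tree Biomass Estimation and Bioenergy Feedstock Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates standing-dead tree biomass after regional forest
    die-off by fusing aerial-survey mortality polygons (per-polygon dead-tree
    counts) with 30-m forest-structure rasters (live trees, biomass and stem
    volume per hectare), in paired detection-threshold variants that bracket
    the aerial detection limit. Screens the resulting dead-biomass grid for
    recoverable bioenergy feedstock via density-based spatial clustering,
    wilderness exclusion, tree-size and dead-tree-density filters; classifies
    the remainder by expected harvest cost (chipping size class, terrain
    slope, road proximity, hazard-zone tier); converts totals to electricity
    potential and carbon mass; and validates polygon-level estimates against
    an independent biomass-loss raster with log-scale RMSE. Includes a
    seeded synthetic-landscape generator with retained ground truth so the
    whole pipeline is testable without proprietary survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
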