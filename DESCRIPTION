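Package: wlfmap
Title: Modelling Woody Linear Features Along Field Boundaries from Canopy Height Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map hedges and lines of trees (woody linear features)
    along field boundaries from paired terrain and surface altitude grids.
    Derives a canopy height model by differencing, masks land cover and high
    altitude areas where such features do not occur, dissolves a field-polygon
    mosaic into a noded boundary line network, attributes each boundary segment
    with canopy height statistics sampled along its length, and classifies
    segments as woody or other by a three-threshold height rule. Includes
    stratified expansion of per-square woody lengths to national totals, a
    sequential 0.01-m coordinate search that calibrates the thresholds against
    survey length estimates, a buffered point-sampling validation procedure
    with confusion matrices, percent agreement and Cohen's kappa, density
    mapping, and a seeded synthetic landscape generator with known ground
    truth for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
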