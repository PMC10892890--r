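Package: insulametrics
Title: Geospatial Drivers of Plant Endemism on Mediterranean Islands
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for modelling vascular-plant richness and the
    proportion of narrow endemics on Mediterranean islands and archipelagos.
    Provides two gridded geospatial metrics (an index of topographic
    roughness from elevation grids, and a surrounding-landmass isolation
    index from binary land/sea rasters), a packaged eight-island dataset,
    negative binomial and beta regression with small-sample
    information-criterion model selection over predictor subsets, and seeded
    synthetic-data generators (terrain, coastlines, island tables) for
    end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
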