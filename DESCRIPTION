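Package: paleoveg
Title: Paleovegetation Hindcasting with Presence-Background Niche Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct past vegetation distributions from
    bioclimatic grids. Characterizes vegetation units climatically,
    screens predictor collinearity with Spearman rank correlation, fits
    L1-regularized maximum-entropy niche models from presence and
    background samples, projects fitted models onto past climate slices
    with a linear CO2 physiological correction, composites per-unit
    suitability surfaces into categorical vegetation maps with a
    no-analog class, summarizes areas and elevation limits through time,
    and validates hindcasts against grouped fossil-pollen percentage
    series. Includes a synthetic-landscape generator (elevation-driven
    lapse-rate climate, altitudinal vegetation belts, glacial anomalies,
    CO2 ramp, distance-decayed pollen assemblages) so the full pipeline
    is testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
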