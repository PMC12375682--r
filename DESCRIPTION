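Package: sdmscape
Title: Presence-Only Species Distribution Modelling with Spatial Block
    Cross-Validation and Environmental Pseudo-Absence Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for presence-only species distribution modelling on
    gridded predictor stacks: raster predictor preparation (water masking,
    bilinear resampling, temporal median compositing, road-buffer
    rasterisation, radar backscatter decibel conversion, vegetation
    indices, land-cover one-hot expansion), pseudo-absence generation by
    k-means environmental profiling, a ten-iteration spatial-block
    cross-validated random-forest ensemble producing habitat suitability
    index (HSI) maps with majority-vote binary maps and variable
    importances, threshold-independent validation metrics (AUC-ROC,
    AUC-PR, sensitivity, specificity), interannual change detection and
    suitable-area accounting, and a synthetic-landscape generator with
    spatially autocorrelated predictors, road-biased presence sampling
    and a known true suitability surface for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
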