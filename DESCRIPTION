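Package: yieldkrige
Title: Hybrid Village-to-Pixel Crop Yield Disaggregation with Residual Kriging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for disaggregating administrative (village-level) crop yield
    statistics to pixel scale. Fits regression, tree-ensemble and two-branch
    recurrent (LSTM/GRU) downscaling models on zonally aggregated satellite-band,
    weather and soil covariates, then corrects systematic spatial bias by
    ordinary kriging of village-level residuals under a cross-validated
    semivariogram model. Includes traditional NDVI weight-based and
    percentile-based allocators, an area-to-point kriging surrogate, a
    synthetic-landscape simulator with known pixel-level truth, and evaluation
    machinery (regression metrics, Friedman/Nemenyi rank tests, Moran's I with
    k-nearest-neighbour weights).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    glmnet,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
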