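Package: uavlai
Title: Winter Wheat Leaf Area Index Estimation from UAV Hyperspectral Imagery
Version: 0.1.0
Authors@R: person("Analytics", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating winter wheat leaf area index
    (LAI) from UAV-type hyperspectral canopy reflectance. Provides sensor
    band-grid arithmetic and Gaussian spectral-response resampling,
    reliable-band trimming, first-derivative correlation screening, the
    successive projections algorithm (SPA), competitive adaptive reweighted
    sampling (CARS) and their SPA-then-CARS chain for characteristic-band
    selection, three regression back-ends (partial least squares, RBF
    support vector regression, second-order gradient-boosted trees) with
    grid-searched hyperparameters, accuracy evaluation by R2/RMSE/RPD with
    an area-based calibration/validation split, and a synthetic canopy
    spectrum generator so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
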