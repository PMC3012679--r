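Package: benthicstocks
Title: Global Seafloor Standing-Stock Modelling with Regression Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for modelling and mapping global seafloor standing stocks
    (biomass and abundance of benthic size classes) from gridded environmental
    predictors. Implements partial-regression depth-trend analysis with
    latitude/longitude detrending, a bootstrap regression random forest with
    out-of-bag error and accuracy-based permutation importance, a
    coverage-threshold scenario ensemble, and global predictive mapping with
    inverse-distance-weighted smoothing, Jenks natural-breaks classification,
    and area-weighted (cosine-latitude) global and zonal integrals. A synthetic
    world generator produces bathymetry, correlated predictor grids, satellite
    coverage fields, and stock records with known generative parameters so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
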