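Package: gwrshed
Title: Nested Sub-Watershed Water-Quality Analysis with Geographically
    Weighted Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the effect of land use on river water
    quality over a nested sub-watershed hierarchy. Implements the
    upstream-corrected electrical-conductivity statistic (delta-EC): the
    EC observed at a sub-watershed pour point minus the catchment-area
    weighted contribution of its directly upstream sampling sites, which
    isolates the local sub-watershed's contribution to the ionic load.
    Provides land-use predictor construction from category rasters or
    count tables, exhaustive enumeration of predictor subsets under
    forest-subdivision constraints, global least-squares fits with VIF
    diagnostics, geographically weighted regression with fixed-distance
    Gaussian or bisquare kernels, leave-one-out CV and corrected-AIC
    bandwidth selection, approximate F tests for spatially varying
    coefficients, global Moran's I residual diagnostics, a codified
    model-selection rule, and a synthetic dendritic-watershed generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ape,
    car,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
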