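Package: trscape
Title: Tikhonov-Regularized Random Landscapes for Subgrid Vegetation and
    Carbon Flux Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates spatially autocorrelated random fields of the
    normalized difference vegetation index (NDVI) from a single coarse
    pixel's mean and variance using two-dimensional Tikhonov
    regularization, in which a penalty on first differences between
    cardinal neighbors (weighted by a Lagrange multiplier gamma) imposes
    spatial smoothness on an otherwise uniform random draw.  Provides
    geostatistical tools to characterize the generated and observed
    fields (isotropic Matheron semivariograms, spherical variogram model
    fits, radially averaged power spectra) and to calibrate gamma against
    a target semivariogram range through a generalized logistic curve.
    Downstream, NDVI maps are converted to leaf area index via an
    exponential transfer function and propagated to gross primary
    productivity with an aggregated canopy light-response model (PLIRTLE)
    driven by photosynthetic photon flux density, including four methods
    for classifying vegetation patch edges and applying an edge-related
    productivity reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
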