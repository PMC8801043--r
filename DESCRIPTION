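Package: morphoscar
Title: Morphoelastic Simulation and Neural Surrogates for Post-Burn Scar Contraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates post-burn scar contraction with a one-dimensional
    morphoelastic continuum model (signalling molecules, fibroblasts,
    myofibroblasts and collagen coupled to tissue mechanics), discretised
    with linear finite elements on a moving mesh and integrated with
    backward Euler and Picard iterations. Provides a stability-constrained
    uniform sampler and corpus generator for the 25 patient- and
    wound-specific parameters, a feed-forward neural surrogate
    (25-100-100-365, rectified-linear hidden layers, sigmoid output)
    trained with Adamax, learning-rate decay and early stopping, a
    learning-rate range test across optimizers, multi-target regression
    metrics (R squared, aRRMSE, aRelErr, MAE) with cross-validation
    reports, and Monte-Carlo uncertainty propagation of the predicted
    relative surface area course.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
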