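Package: deepcdm
Title: Exploratory Deep Cognitive Diagnosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fitting of deep cognitive diagnosis models (DeepCDMs):
    multi-layer directed generative models in which stacked layers of
    binary latent attributes successively generate binary item
    responses, with each adjacent pair of layers forming a cognitive
    diagnosis model (main-effect, all-effect, or DINA). Provides a
    layer-wise L1-penalized EM estimator with coordinate-descent
    M-steps, a non-iterative spectral (truncated SVD plus Varimax)
    initializer, Q-matrix recovery rules, BIC selection over a
    regularization path, a confirmatory mode with known Q-matrices, a
    brute-force classical EM baseline for small models, a forward
    simulator, and label-switching-aware recovery metrics for
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
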