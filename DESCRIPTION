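Package: gaitxai
Title: Interpretable Convolutional Classification of Ground-Reaction-Force Gait Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gait deterioration from spatiotemporal
    ground-reaction-force (GRF) recordings. Provides a synthetic gait
    generator with a clinical stance/swing phase model and plantable
    class-discriminative event effects, windowing and standardization of
    raw force-platform recordings, a typed convolutional layer graph with
    Adam training, layer-wise relevance propagation (LRP) with epsilon,
    alpha-beta, flat and deep-Taylor rule composites plus gradient
    saliency baselines, most-relevant-first (MoRF) perturbation curves for
    model and explanation-method selection, and assignment of relevance
    peaks to the named gait-cycle events A-G.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    class,
    kernlab
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
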