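Package: uqsa
Title: Uncertainty Quantification and Sensitivity Analysis for Black-Box
    Neuroscience Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Propagates parameter uncertainty through black-box simulation
    models using polynomial chaos expansions (point collocation and
    pseudo-spectral projection) or quasi-Monte Carlo sampling with Saltelli's
    scheme, and attributes output variance to individual parameters via
    first- and total-order Sobol indices. Handles statistically dependent
    parameters through the Rosenblatt transformation, extracts
    electrophysiological features (action-potential shape and spike-train
    statistics) so that uncertainty can be quantified on salient model
    behaviour rather than raw traces, and ships dependency-free reference
    models: a cooling coffee cup, the original Hodgkin-Huxley membrane model,
    and a sparsely connected recurrent network of integrate-and-fire neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    parallel,
    purrr,
    Rcpp,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
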