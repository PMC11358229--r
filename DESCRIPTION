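Package: emosearch
Title: Hierarchical Bayesian Analysis of Emotional Visual-Search Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for visual-search experiments on
    the anger superiority effect. Generates trial-level search data with a
    known ex-Gaussian reaction-time structure and an equal-variance
    signal-detection observer, filters outliers with Tukey fences, fits
    hierarchical Bayesian ex-Gaussian and signal-detection models by MCMC,
    and performs credible-interval and standardized effect-size inference.
    Also implements the stimulus-validation computations used to equate
    displays: Itti-Koch bottom-up saliency maps with a Monte-Carlo
    saliency-index simulation over 3x3 face grids, and a block-reduction
    image-motion metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    coda,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
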