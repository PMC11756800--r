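Package: patternfit
Title: Model Selection and Simulation-Decoupled Posterior Estimation for
    Biological Pattern Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for data-driven analysis of biological pattern formation
    from steady-state snapshot images.  Provides a suite of pattern-forming
    simulators (Turing reaction-diffusion, kernel-based Turing, Gray-Scott,
    Edwards-Wilkinson, Eden, diffusion-limited aggregation, L-systems,
    phase-field and Cahn-Hilliard models), image preprocessing and a
    deterministic spectral image encoder, cosine-similarity retrieval of
    candidate mathematical models scored by mean average precision,
    contrastive metric learning of a two-dimensional reduced feature space,
    and Simulation-Decoupled Neural Posterior Estimation (SD-NPE):
    approximate Bayesian parameter inference that combines per-image
    probabilistic-regressor posteriors on a parameter lattice.  Closed-form
    Turing linear-stability analytics (dispersion relation, fastest-growing
    wavenumber, unstable band width) serve as independent oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
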