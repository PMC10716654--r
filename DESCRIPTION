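Package: paleorange
Title: Process-Explicit Reconstruction of Megafauna Range and Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct millennial-scale range and population
    dynamics of a large herbivore from fossil occurrences, palaeoclimate
    layers and reconstructions of human abundance. Implements a Gaussian
    hypervolume niche model with cross-validated bandwidths and niche
    subsampling, bounded human-pressure surfaces with lognormal sampling, a
    stochastic spatially explicit population model (Ricker growth, Allee
    extirpation, friction-limited dispersal, saturating harvest), pattern-
    oriented validation by approximate Bayesian computation with iterative
    prior refinement, counterfactual scenario attribution, and penalized
    smooth-regression driver analysis, together with synthetic-landscape
    generators with known truth for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    mgcv,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
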