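Package: surfpmf
Title: Umbrella Sampling, WHAM and Free-Energy Decomposition for Solute
    Surface Propensity at a Slab Interface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct a potential of mean force (PMF) along a
    slab-normal reaction coordinate from harmonically biased umbrella
    windows via the weighted histogram analysis method (WHAM), to decompose
    the resulting adsorption free energy into enthalpic and entropic terms
    and the enthalpy into water-water, solute-water and solute-solute
    interaction components, and to run the structural analyses that
    accompany such studies: slab density profiles and the Gibbs dividing
    surface, geometric hydrogen-bond counting, side-chain orientation
    distributions and intramolecular close-pair searches. A synthetic
    overdamped-Langevin slab system with a known free-energy landscape
    exercises the full chain end to end, so every estimator can be checked
    by parameter recovery against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
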