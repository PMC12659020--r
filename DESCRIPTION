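Package: deltamd
Title: Delta-Learning Potentials and Molecular Dynamics for Liquid Water
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for building short-ranged delta-learning
    corrections that lift a cheap baseline potential to a higher-level
    potential-energy surface in condensed-phase simulation. Provides a
    synthetic two-level theory for flexible water whose difference is
    strictly short-ranged, whole-molecule cluster carving from periodic
    snapshots, cumulative multi-radius training sets labelled with
    energy-only differences, a ridge-regression correction model on
    rotation-invariant atomic descriptors with analytic forces, a
    velocity-Verlet molecular dynamics engine with stochastic velocity
    rescaling (CSVR) thermostat and stochastic cell rescaling barostat,
    and estimators for densities, radial distribution functions and
    finite-size-corrected self-diffusion, together with a radius
    convergence protocol that validates the composite model against a
    directly simulable high-level reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
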