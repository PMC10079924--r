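Package: biofilmpin
Title: Individual-Based Biofilm Growth Simulation and Interface Pinning Analysis
Version: 0.1.0
Authors@R:
    person("biofilmpin", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A 2D individual-based model of biofilm growth in a flow-cell-like
    geometry (disc-shaped cells with Monod kinetics coupled to a steady-state
    nutrient reaction-diffusion field, stochastic division, mechanical shoving,
    and periodic clipping of inactive deep biomass), together with the spatial
    analysis machinery needed to study the fingering transition of the biofilm
    interface: active-layer morphometrics on an 8 micron grid, multi-valued
    interface roughness that accounts for overhangs, the pinned interface
    fraction, autocorrelation-corrected steady-state statistics, kymographs,
    dimensionless control parameters, and phase-diagram assembly across
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
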