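Package: phototunnel
Title: Voxel Monte Carlo Simulation of Heat-Induced Light-Delivery
    Tunnels in Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weighted-photon-packet Monte Carlo transport through voxelized
    turbid phantoms, built to study photothermal enhancement of light
    delivery: a locally heated cylindrical "tunnel" with a reduced,
    temperature-dependent scattering coefficient guides more light to depth.
    Provides a linear temperature-to-scattering calibration for lipid
    phantoms, scenario builders for single-layer and four-layer graded
    heating tunnels, a Henyey-Greenstein voxel transport engine with
    Russian roulette and an energy-conservation ledger, paired
    common-random-number runs for percent fluence-improvement statistics,
    and closed-form validation oracles (Beer-Lambert, diffusion
    approximation, phase-function moments).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
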