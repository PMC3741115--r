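Package: dopaflux
Title: Stochastic Reaction-Diffusion Simulation of Cortical Dopamine
    Volume Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates non-synaptic dopamine signalling in primate prefrontal
    cortex: stochastic quantal release from sparse, randomly placed sites on a
    3-D voxel grid, Fickian diffusion through tortuous extracellular space, and
    linear transporter reuptake, advanced with an explicit Euler
    finite-difference scheme. Ships closed-form well-mixed predictions that
    serve as an independent oracle, protocol presets for tonic and phasic
    firing, Parkinsonian-like release-site depletion and complete reuptake
    block, and analysis tools for volume statistics, difference maps, line
    profiles, distance-resolved concentration traces and two-state receptor
    occupancy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
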