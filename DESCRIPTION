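Package: dsdfibril
Title: DNA Strand-Displacement Circuits Driving Transient Origami Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for toehold-mediated DNA strand-displacement (DSD)
    reaction networks that cross-regulate two self-sorting DNA-origami fibril
    species. Represents strands and complexes at the domain level, enumerates
    the mass-action reaction network reachable from an initial species set,
    assigns toehold-limited rate constants, integrates the network
    deterministically (stiff ODE) or stochastically (Gillespie SSA), maps
    trajectories to normalized fluorophore/quencher fluorescence proxies, and
    couples the connector-state kinetics to a stochastic reversible step-growth
    assembly model producing fibril length distributions and number-average
    degrees of polymerization. Ships the negative-feedback, amplifier (fuel A/B)
    and threshold circuit presets together with a calibrated default parameter
    set, SBML and CSV export, and ggplot2 visualisation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
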