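Package: minorgroove
Title: DNA Minor-Groove Shape and Electrostatics Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of DNA minor-groove shape readout by minor-groove-binding
    proteins. Reads protein-DNA complex coordinates (PDB/mmCIF), identifies
    Watson-Crick base pairs and fits standard base reference frames, computes
    intra-base-pair and base-pair-step helical parameters (propeller twist,
    helical twist, roll, ...), measures minor-groove width profiles by the
    cross-strand phosphate distance method, solves the finite-difference
    linearized Poisson-Boltzmann equation for the electrostatic potential at
    groove midpoints, and correlates groove narrowing with electrostatic
    focusing. Includes an all-atom B-form DNA duplex builder driven by helical
    parameter profiles (narrow-groove TA-like and wide-groove GC-like presets),
    Kabsch rigid-body superposition, and single-site Kd fitting of NMR
    chemical-shift-perturbation titrations, so the entire pipeline is testable
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
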