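Package: coilsim
Title: Coarse-Grained Simulation of Designed Coiled-Coil Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sticker-and-spacer simulation and analysis pipeline for de novo
    designed coiled-coil (CC) phase-separating proteins. Polypeptides are
    encoded as ordered coil and linker segments, coarse-grained to one bead
    per residue, and simulated with orientation- and registry-aware sticky
    interactions under Langevin dynamics. A slab phase-coexistence protocol,
    density-profile and cluster-size analyses, MSD-based diffusion estimates
    with bootstrap errors, and coil-engagement statistics classify each design
    as condensate-forming, dimer-poisoned, or diffuse, reproducing the design
    rules (valency, arrangement mismatch, heptad length, orientation
    patterning, third-chain inhibition) that govern coiled-coil-driven
    liquid-liquid phase separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
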