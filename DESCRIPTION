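Package: nucleoslide
Title: Coarse-Grained Modelling and Analysis of Nucleosome Sliding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying nucleosome repositioning with coarse-grained
    (one bead per amino acid, three beads per nucleotide) models. Implements a
    sliding-invariant geometric histone-DNA hydrogen-bond potential,
    excluded-volume and Debye-Hueckel interaction energies, trajectory analysis
    coordinates for DNA sliding (zeta) and rotation (eta) built on a
    spline-based DNA helical-axis extraction, residence distributions and
    free-energy surfaces with hydrogen-bond-strength reweighting, and small
    Markov-chain kinetic models (mean first passage times, Gillespie
    simulation) of repositioning routes. A synthetic-fixture generator builds
    idealized superhelical nucleosomes and screw-like, jump-like and loop-like
    sliding trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
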