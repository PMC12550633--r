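Package: hbnet
Title: Kinetics and Bayesian Design Optimization of Hole-Bifurcation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Microstate master-equation simulator for light-driven hole
    bifurcation on designed redox cofactor networks. Hole hops are modeled
    with vibronic (Marcus-Jortner) nonadiabatic rates and an exponential
    distance decay of the electronic coupling; hole-hole repulsion at the
    bifurcating tryptophan dimer energizes the "hot" hole. Provides the
    bifurcation quantum yield, terminus arrival curves and completion times,
    a from-scratch Gaussian-process surrogate with upper-confidence-bound
    acquisition for optimizing cofactor potentials and edge distances, the
    snapshot repulsion-energy bookkeeping that sets the pair interaction, and
    contact-geometry statistics (closest H-H distance, indole inter-plane
    angle, projected ring overlap area) for tryptophan pairs from PDB
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    yaml,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
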