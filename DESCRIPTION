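Package: cgslab
Title: Coarse-Grained Slab Simulations of Biomolecular Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how molecular mass changes (isotope-style bead-mass
    scaling and non-interacting glycine insertions) alter liquid-liquid phase
    separation of intrinsically disordered protein segments. Implements a
    bead-per-residue coarse-grained model of FUS prion-like and RGG domains with
    harmonic bonds, a weak 12-6 Lennard-Jones potential and Debye-Hueckel
    electrostatics, Langevin dynamics in the direct-coexistence slab geometry,
    and the associated phase, mobility, conformation and contact observables:
    windowed density profiles and their high-low difference, chain z motion
    rates, interfacial flux, head-to-tail distances, electrostatic contact
    counts, and critical-temperature estimation by threshold interpolation or a
    power-law binodal fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    minpack.lm,
    optparse
Config/testthat/edition: 3
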