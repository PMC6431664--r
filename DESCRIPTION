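Package: memprobe
Title: Fluorescence, Calorimetry and Bilayer-Structure Analysis of
    Small-Molecule/Membrane Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces membrane-biophysics measurements of small-molecule
    partitioning into lipid bilayers to their standard observables. Computes
    laurdan generalized polarization melting curves with phase-transition
    temperature estimation and DPH fluorescence anisotropy from polarized
    intensity quadruplets; fits isothermal titration calorimetry
    lipid-into-solute titrations to a one-parameter partition model and
    derives the transfer thermodynamics (K, enthalpy, entropy, free energy
    under a mole-fraction standard state); and computes structural
    observables of bilayer coordinate trajectories (per-carbon deuterium
    order parameters via united-atom hydrogen reconstruction, atomic-group
    z-profiles relative to the bilayer center of mass, and phosphate-plane
    thickness). A seeded synthetic-data generator emulates each experiment
    so every stage is testable end to end, and a pipeline driver ties the
    stages into reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
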