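Package: hgbind
Title: Host-Guest Binding Thermodynamics for Cucurbit[7]uril Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for host-guest binding studies of
    cucurbit[7]uril (CB[7]) with phenylpiperazine-type guests. Fits
    one-site isothermal titration calorimetry (ITC) isotherms with the
    standard cumulative-heat model, assembles multi-term binding free
    energies (interaction, dispersion, solvation, entropic and
    deformation contributions) with Boltzmann averaging over binding
    conformers, classifies bond-critical-point interactions from QTAIM
    tables (Cremer-Kraka local energy densities, Hayashi and Jeffrey
    schemes, Afonin interaction energies), computes crystallographic
    binding-pose descriptors from occupancy-aware coordinates, and
    correlates computed with experimental thermodynamics. Includes
    synthetic-data generators with embedded ground truth so every stage
    of the pipeline is testable without instrument or quantum-chemistry
    output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
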