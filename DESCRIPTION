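Package: nanoject
Title: Coarse-Grained Simulation and Single-Molecule Counting for Nanopipette
    DNA Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the delivery of DNA from a conical glass
    nanopipette into crowded and uncrowded baths. Provides a coarse-grained
    bead-spring DNA model, Lennard-Jones crowders (bovine serum albumin),
    an overdamped Brownian dynamics engine driven by voxelised steric and
    electrostatic potential grids, a steric-exclusion-model estimator of the
    ionic current with DNA conductivity enhancement and crowder mobility
    masking, ensemble analyses of translocation (base pairs exited, radius of
    gyration, centre-of-mass distance, crowder displacement), a synthetic
    generator of ionic current traces with planted translocation events, and
    the single-molecule counting stage: asymmetric-least-squares baseline
    tracking, threshold event detection and per-event dwell, amplitude and
    equivalent-charge metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
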