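Package: cyp51md
Title: Desk-Scale Analysis of CYP51A1 Variant Molecular Dynamics and
    Variant Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics studies of
    lanosterol 14-alpha-demethylase (CYP51A1) missense variants and their
    interaction with the substrate lanosterol and the redox partner POR
    (cytochrome P450 oxidoreductase). Implements hydrogen-bond occupancy
    statistics of the lanosterol hydroxyl group under a distance criterion,
    heme-iron to C30 distance monitoring, trajectory-average binding-enthalpy
    estimation with block-averaged uncertainties, key-residue contact scoring
    and ranking of CYP51A1-POR docking poses, and classification, filtering
    and counting of missense/nonsense variant tables annotated with SIFT and
    PolyPhen-2 scores. A seed-deterministic synthetic-data generator produces
    trajectories, autocorrelated energy series and decoy pose sets with known
    ground truth so that every analysis stage is testable without
    cluster-scale simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'selection.R'
    'structure-io.R'
    'hbond.R'
    'geometry.R'
    'binding-energy.R'
    'pose.R'
    'variants.R'
    'tables-data.R'
    'synthetic.R'
    'cli.R'
    'show-methods.R'
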