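Package: MechanoBond
Title: Mechano-Regulation Analysis of Receptor-Ligand Interface Bonds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the force-dependent stability of a two-chain
    receptor-ligand complex from molecular dynamics trajectories and
    single-molecule force spectroscopy. Detects interface hydrogen bonds
    and salt bridges with geometric criteria, computes per-bond
    occupancies, and propagates them through an independence-based
    dissociation-probability model to complex-level dissociation and its
    force-normalised form. Classifies per-bond occupancy-versus-force
    patterns (slip, catch-slip, slip-catch-slip, catch-slip-catch),
    locates transition forces, and provides structural mechano-metrics
    (superposed C-alpha RMSD, Shrake-Rupley and buried interface SASA,
    inter-helix angle, centroid distances), rupture-force extraction from
    pulling traces, lifetime binning with two-pathway catch-slip fitting,
    and seeded synthetic generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'occupancy-io.R'
    'dissociation.R'
    'force-response.R'
    'selections.R'
    'traj-io.R'
    'interactions.R'
    'lifetimes.R'
    'metrics-geometry.R'
    'metrics-sasa.R'
    'metrics-superpose.R'
    'pipeline.R'
    'synthetic.R'
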