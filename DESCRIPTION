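Package: voxscreen
Title: Structure-Based Virtual Screening with Voxel-Grid Convolutional Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structure-based virtual-screening pipeline: binding-site
    definition by a flooding algorithm on an occupancy lattice, rigid-body
    ligand pose sampling with steric-clash rejection, rasterization of
    protein-ligand poses into fixed-size multi-channel voxel grids, a 3D
    convolutional neural network scoring model trained on pK affinity labels
    with Boltzmann-weighted pose-ensemble averaging, and a post-screen
    compound triage cascade (top-K selection, property and SMARTS filters,
    ECFP4/Butina diversity clustering, Lipinski and Veber drug-likeness
    rules, PAINS flags). Includes structure-model quality checks (Kabsch
    superposition RMSD, steric-clash detection, pLDDT confidence banding)
    and a synthetic-data module that generates toy pockets, ligand sets with
    known ground-truth affinities and screening libraries with planted
    triage outcomes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
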