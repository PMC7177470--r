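Package: vsensemble
Title: Consensus Scoring and Structural Statistics for Ensemble Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-docking analysis toolkit for structure-based virtual
    screening against multi-conformation, multi-subunit receptor targets.
    Builds enrichment-factor-optimized (EFO) consensus models, i.e. linear
    combinations of up to four docking/rescoring score columns whose
    coefficients are chosen to maximize the enrichment factor at a fixed
    top fraction (EF 1% by default), and drives a progressive ensemble
    protocol over the monomers and molecular-dynamics frames of an
    oligomeric target. Also provides the structural statistics used to
    pick and interpret receptor frames: Kabsch superposition, binding-site
    RMSD profiles and frame selection, Shrake-Rupley solvent-accessible
    surface areas, the inter-monomeric contact surface, and pairwise
    electrostatic/Lennard-Jones interaction energies. A synthetic campaign
    generator with planted signal structure supports testing and parameter
    recovery without proprietary screening data.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
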