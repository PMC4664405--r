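Package: xlmapr
Title: Cross-Linking Mass Spectrometry Mapping and Restraint-Based Docking
    Pose Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping protein-protein interactions from lysine
    cross-linking mass spectrometry (XL-MS) and for turning identified
    cross-links into structural restraints.  Covers in-silico tryptic
    digestion with decoy generation, enumeration and scoring of BS3
    cross-linked peptide pairs against MS/MS peak lists (MGF), target-decoy
    FDR estimation, distance-restraint evaluation on PDB coordinate models
    with an internal-control cross-link, coarse-grained sampling of missing
    C-terminal tail residues, screening of docking pose ensembles,
    single-ligand bridging feasibility (mutual-exclusivity) analysis, and
    bound/input co-immunoprecipitation densitometry statistics.  Includes
    seeded synthetic-data generators for every input so the whole pipeline
    is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
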