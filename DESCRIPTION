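Package: foldmimic
Title: Secondary-Structure Mimicry Analysis for Small-Molecule Conformer
    Ensembles and Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether the conformers of a flexible
    scaffold (e.g. a hydantoin-based peptidomimetic) project their
    substituents like the side chains of protein secondary structures.
    Provides energy-window filtering of conformer ensembles; geometric
    classifiers for alpha-helix, beta-turn and 3-10-helix mimicry based on
    anchor-atom distances, a turn dihedral and intramolecular hydrogen
    bonds (C10/C7 pseudo-cycles); construction of ideal helix and
    beta-turn (types I, II, I', II') backbone templates and reflection-free
    Kabsch RMSD fitting against them; molecular-formula arithmetic
    (average and monoisotopic mass, elemental analysis, electron counts,
    F(000), cell volume, crystal density); crystal-structure input (CIF),
    symmetry expansion and hydrogen-bond tables; and Hirshfeld-surface
    contact statistics (random contacts, enrichment ratios, globularity,
    normalized contact distance, fingerprint binning). A synthetic-data
    generator plants conformer ensembles, toy crystals and contact tables
    with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    igraph,
    jsonlite,
    yaml,
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
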