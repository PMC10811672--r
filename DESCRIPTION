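Package: funcfix
Title: Function-Preserving Protein Redesign Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the fixed-position stage of function-preserving protein
    sequence redesign and for analysing the downstream characterization data.
    Builds fixed-position design masks from ligand first-shell proximity and
    multiple-sequence-alignment conservation and emits them in the
    ProteinMPNN fixed-position dialect; triages candidate designs by
    prediction confidence (pLDDT) and C-alpha RMSD to the parent structure
    after Kabsch superposition; fits Michaelis-Menten kinetics, thermal melt
    curves and benchtop activity-retention series; and summarises
    conformational ensembles by per-residue RMSF and catalytic-dyad distance
    populations. A fixtures module generates synthetic inputs with planted
    ground truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
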