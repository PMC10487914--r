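Package: cycbinder
Title: Design and Evaluation of Head-to-Tail Cyclic Peptide Binders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing and evaluating head-to-tail cyclic peptide
    binders against protein targets. Builds relative-position offset matrices
    for structure predictors in which the target protein block keeps the
    default linear encoding while the peptide block wraps cyclically
    (including the inter-chain break used for complex prediction); evaluates
    predicted or designed peptides against native peptides with
    cyclic-permutation-aware windowed C-alpha RMSD; triages candidate designs
    by per-residue confidence (pLDDT) and SASA-normalized interface energy
    parsed from Rosetta InterfaceAnalyzer score tables; and assembles
    3D-alignment-based gapped sequence alignments with per-column information
    content for sequence logos. A synthetic-fixture generator produces
    structures, confidence files and score tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
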