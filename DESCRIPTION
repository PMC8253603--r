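Package: structmat
Title: Structural Scoring Matrices for MHC Class II Peptide Binders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds position-specific scoring matrices for the 9-mer core of
    peptides bound to MHC class II receptors from structural observables
    (main-chain hydrogen bonds and non-bonded contacts) measured over
    conformational ensembles, and uses them to predict the sign of
    binding-activity differences caused by single-point mutations. Includes
    multi-model PDB ensemble I/O, geometric hydrogen-bond and contact
    detection, side-chain dihedral monitoring with Kullback-Leibler
    comparison of angle distributions, frame-selection strategies, core
    prediction from sequence matrices, a multi-method consensus rule, a
    conditional-"or" method combination, bootstrap evaluation, and a
    synthetic-data generator producing toy complexes and planted peptide
    cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
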