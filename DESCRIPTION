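Package: synbinder
Title: Data-Efficient Classification and Library Triage of Alpha-Synuclein Fibril Ligands
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A ligand-based virtual-screening toolkit for binary binder/non-binder
    classification of small molecules against alpha-synuclein fibrils from
    censored radioligand-displacement Ki measurements. Provides native SMILES
    parsing and canonicalization, ECFP-style hashed circular (Morgan)
    fingerprints with Tanimoto similarity, a panel of 2D physicochemical and
    topological descriptors, Ki-threshold labeling with censoring, stratified
    splitting, cross-validated model selection (logistic regression, k-nearest
    neighbours, decision tree) optimizing macro F1 with leak-free in-fold
    feature selection, a maximum-Tanimoto similarity baseline classifier,
    scaffold-aware library curation with diversity-oriented prospective set
    selection, a synthetic scaffold-decoration benchmark generator with a
    latent similarity-driven affinity model, and an end-to-end reporting
    pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
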