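Package: khibkit
Title: Prediction of Lysine 2-Hydroxyisobutyrylation Sites from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for predicting lysine 2-hydroxyisobutyrylation
    (Khib) sites from protein sequence. Builds padded lysine-centred peptide
    windows from FASTA proteomes and site tables, removes redundancy by greedy
    identity clustering, and balances classes by cluster sampling. Encodes
    windows as hybrid feature vectors combining composition/transition/
    distribution (CTD) descriptors, position-specific AAindex physicochemical
    scales, and mean-pooled residue embeddings from a pluggable provider;
    ranks features by an empirical mutual-information estimator and trains a
    gradient-boosted decision-tree classifier with leaf-wise tree growth.
    Includes stratified cross-validation, confusion-matrix metrics, ROC/AUC,
    Hanley-McNeil comparison of correlated AUCs, two-sample sequence-logo
    position statistics, internal cluster-quality indices, and a synthetic-data
    generator with species presets for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    cluster,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
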