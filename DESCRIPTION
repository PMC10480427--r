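Package: epitopeGA
Title: Linear B-Cell Epitope Classification with Genetic-Algorithm
    Feature Selection and an Instance-Based Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies peptide sequences as linear B-cell epitopes (LBCE)
    from amino-acid k-mer composition. Sequences are encoded as unigram,
    bigram and trigram count vectors over the 20-letter amino-acid
    alphabet (8420 features plus the class label). A two-part genetic
    algorithm first searches for a stratified train/test partition that
    maximizes inter-class feature variance, then searches for an optimal
    sequence truncation length scored by the test accuracy of a
    linear-kernel support vector classifier. Classification uses a
    parallel instance-based ensemble of 1-nearest-neighbour, random
    forest, logistic regression and support vector machine: the union of
    correctly classified instances defines the ensemble's oracle
    accuracy, and new sequences are routed to the base classifier whose
    stored correct instances correlate best with the query, with optional
    self-augmentation of the training pool for near-duplicate queries.
    Includes a seeded synthetic peptide generator with planted
    compositional signal, evaluation metrics (accuracy, precision,
    recall, F-measure, ROC/AUC), and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    SparseM,
    e1071,
    jsonlite,
    ranger,
    stats,
    utils,
    withr,
    yaml
Suggests:
    class,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
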