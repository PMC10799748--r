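Package: kmalsite
Title: Lysine Malonylation Site Prediction from Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds benchmark datasets of lysine malonylation (Kmal) sites
    from protein sequences and site annotations, encodes lysine-centered
    peptide windows with a battery of sequence, evolutionary and
    physicochemical descriptors (EAAC, EGAAC, CKSAAP, BLOSUM62, PSSM-derived
    and others), trains a uniform layer of classifiers (random forest, SVM,
    KNN, gradient boosting, a dense network and an LSTM) and combines four of
    them in an equal-weight soft-voting hybrid.  Includes a leak-free
    cross-validation and evaluation harness (accuracy, sensitivity,
    specificity, precision, F1, MCC, Cohen's kappa, ROC and PR curves) and a
    seeded synthetic-data generator with a planted sequence motif so the full
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    class,
    data.table,
    e1071,
    jsonlite,
    methods,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
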