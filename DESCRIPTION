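Package: olimoss
Title: Protein-Specific Prediction of RNA-Binding Protein Targets from
    Sequence, Motif and Secondary-Structure Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether an mRNA (typically a 3'UTR) is bound by a given
    RNA-binding protein (RBP) using per-protein linear support-vector
    classifiers. Implements three feature encodings of increasing complexity:
    Oli (256 tetranucleotide frequencies), OliMo (Oli plus the 10 highest
    position-specific scoring matrix motif scores) and OliMoSS (OliMo plus
    folding energy, stem density, stem count and 256 single-strand
    accessibility indicators derived from dot-bracket secondary structures).
    Includes SMOTE oversampling of the bound class restricted to training
    folds, per-fold grid search of the SVM cost parameter by Matthews
    correlation coefficient, leakage-safe stratified cross-validation with
    per-fold motif construction, AUC/precision/ROC/PR evaluation, Wilcoxon
    signed-rank method comparison, negative-resampling confidence intervals,
    information-gain feature ranking, cross-protein sensitivity matrices, and
    a synthetic planted-motif dataset generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
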