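Package: caaxpred
Title: Prediction of CaaX Motif Prenylation and Cleavage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the 8000 possible C-terminal Cxxx protein motifs as
    non-prenylated, shunted (prenylated only), or cleaved (canonically
    modified) using models trained on yeast genetic screen data. Provides
    curation of positive and negative training sets from screen hit tables,
    three feature encodings for four-residue motifs (one-hot sequence,
    AAindex physico-biochemical properties, and per-token protein
    language-model embeddings through an adapter contract), a
    position-specific scoring matrix with a BLOSUM62-derived background and
    calibrated cutoff, a positional frequency-ratio scorer, four classifier
    families (SVM, naive Bayes, k-nearest neighbours, gradient boosted
    trees) with grid search and Platt-scaled probabilities, stratified
    k-fold cross-validation with standard classification metrics, and
    utilities to scan proteome FASTA files for C-terminal Cxxx motifs and
    partition the full motif space into the three modification classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    class,
    xgboost,
    jsonlite,
    yaml,
    Biostrings
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
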