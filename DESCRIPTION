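Package: phagehost
Title: Predicting Phage-Bacterium Interactions from Genomic Features
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds labelled phage-bacterium interaction corpora
    (family-balanced oversampling of known positives, species-mismatch
    putative negatives, leakage-aware stratified splits), extracts
    fixed-length features for each pair from predicted protein-protein
    interactions (histograms of summed domain-domain interaction scores,
    and physicochemical summaries of protein primary structure), and
    trains grid-searched, 10-fold cross-validated classifiers (k-NN,
    random forest, RBF-SVM, single-hidden-layer neural network) with
    held-out test evaluation. Includes a synthetic-corpus generator with
    a tunable planted receptor-domain signal so the whole pipeline can be
    exercised and benchmarked without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    FNN,
    quadprog,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
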