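Package: phosfuse
Title: Serine Phosphorylation Site Prediction by Fusing Sequence Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts serine phosphorylation sites from protein sequence by
    extracting fixed-width peptide windows around candidate serines, encoding
    them under three complementary schemes (composition of k-spaced amino acid
    pairs, positional one-hot, and amino acid composition), ranking features
    with a two-group Kruskal-Wallis statistic, training per-encoder classifier
    backends (random forest, AdaBoost, support vector machine), and fusing
    their scores with performance-proportional convex weights. Includes
    fixed-false-positive-rate evaluation with partial AUC, a ratio-stratified
    k-fold cross-validation protocol with in-fold feature selection, two-sample
    logo enrichment statistics for window-size diagnostics, and a synthetic
    annotated-proteome generator with planted positional and pair-composition
    signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    ranger,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
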