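Package: homppi
Title: Homology-Based Prediction of Protein-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts physical interaction between two proteins from three
    homology-derived features: sequence similarity to a known interacting
    template pair, a knowledge-based interaction propensity averaged over
    Pfam domain pairs, and the shortest-path weight between homologs of the
    two proteins in a known interaction network. Feature vectors are made
    independent of protein order by half-space selection, discretized with
    the minimum description length entropy method, and classified with an
    Averaged One-Dependence Estimator (with a Naive Bayes baseline).
    Includes random negative-pair sampling, leakage-free stratified k-fold
    cross-validation with ROC, partial AUC, MCC and F-measure metrics, a
    shortest-path-weight distribution analysis, and a synthetic fixture
    generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
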