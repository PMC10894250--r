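Package: woafs
Title: Binary Whale Optimization Algorithm Feature Selection for Clinical Risk Data
Version: 0.1.0
Authors@R: person("woafs", "maintainers", email = "woafs@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for tabular binary-outcome (disease risk)
    data using a binary whale optimization algorithm (WOA): continuous swarm
    search with encircling, logarithmic-spiral and random-search moves, a
    sigmoid transfer function with 0.5 threshold for binarization, a fitness
    function based on stratified 5-fold cross-validated accuracy of an
    L1-penalized logistic model minus a feature-count penalty, and consensus
    (stability) selection over repeated seeded runs with an 80 percent
    frequency threshold. Includes CSV loading with categorical encoding
    schemas, standardization and coefficient-weighting preprocessing, a
    classifier evaluation harness with confusion-matrix metrics, a synthetic
    data generator with planted informative, redundant and noise features, and
    an exhaustive subset-enumeration oracle for validating the search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
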