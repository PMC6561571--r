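Package: rnaswitch
Title: Alternative RNA Secondary Structure Prediction via Conditional
    Base-Pair Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the metastable (alternative) secondary structure of
    RNA switches such as bacterial riboswitches. The conditional-probability
    method first excludes all base pairs within a distance threshold of the
    minimum-free-energy structure, recomputes base-pair probabilities over
    the constrained Boltzmann ensemble with a McCaskill-style partition
    function, selects a longest bulge-tolerant high-probability stem as a
    seed, and folds the alternative structure around that seed by
    constrained energy minimization. A sampling-clustering baseline
    (multi-temperature Boltzmann sampling, 2-means clustering under
    base-pair Hamming distance, silhouette scoring), pooled base-pair
    accuracy metrics, ROC classification, a synthetic bistable-sequence
    generator with known ground truth, and an exhaustive-enumeration oracle
    for validating the dynamic programming are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
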