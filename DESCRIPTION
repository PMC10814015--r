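Package: pnnclass
Title: Probabilistic Nearest Neighbors Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Probabilistic nearest neighbors classification via aggregation of
    nonlocal neighbor-interaction label models. Each rank-r model couples every
    training unit to its r-th nearest neighbor only; its normalizing constant
    is computed exactly in polynomial time from the cycle structure of the
    rank-r neighbor digraph (a functional graph). Per-rank interaction
    strengths are estimated by maximum likelihood, per-rank predictive
    distributions are averaged over the first k ranks, and k is chosen by
    leave-one-out cross-validation. Includes brute-force enumeration oracles
    for tiny instances (exhaustive partition sums, the joint k-neighbor model,
    the max-cut correspondence, and polynomial-coefficient extraction), seeded
    synthetic-data generators, and evaluation utilities (error rate, confusion
    matrix, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
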