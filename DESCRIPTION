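Package: grnbench
Title: Benchmarking Causal Gene Regulatory Network Inference with
    Curated Perturbation Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assembling signed causal gene regulatory networks
    (GRNs) from curated genetic-perturbation evidence via a
    maximum-likelihood mode-of-regulation model, for inferring candidate
    networks from expression profiles (correlation, mutual information,
    ARACNE-style data-processing-inequality pruning, tree-ensemble
    importance), and for quantifying edge-recovery sensitivity and
    specificity with path-tolerant matching, node-label permutation
    nulls, ROC analysis, and perturbation fold-change classification.
    Includes a synthetic-data generator that emulates developmental
    expression compendia and noisy literature evidence so the full
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
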