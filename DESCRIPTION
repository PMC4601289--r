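Package: treepairs
Title: Supervised Network Inference by Classifying Node Pairs with Tree Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers missing edges in partially observed biological networks
    (homogeneous or bipartite) by treating link prediction as supervised
    classification on node pairs. Implements the global approach (one ensemble
    of extremely randomized trees on concatenated node feature vectors) and the
    local approach (per-node single-output models or per-family multi-output
    models), including a two-step procedure that extends the local approach to
    pairs of two unseen nodes. Ships the four-family evaluation protocol
    (cross-validation on pairs and on nodes, AUPR/AUROC scoring, node-degree
    and random baselines), a block-model synthetic network generator with
    controllable feature-structure coupling, tree-leaf bicluster extraction
    and feature-importance reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
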