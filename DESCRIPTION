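Package: dagmm
Title: Subject-Specific Directed Acyclic Graphs via Mixed-Effects Structural
    Equation Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns directed acyclic graphs (DAGs) whose edge strengths vary
    across subjects, by fitting a mixed-effects structural equation model in
    which each directed effect decomposes into a covariate-dependent fixed
    effect and a subject-level Gaussian random effect. Provides the DAG-MM
    procedure: an l1-penalized moment-based sparse skeleton with BIC tuning,
    edge orientation by relative strength, and iterative hard-thresholding
    with acyclicity checking and BIC model selection. Includes a synthetic
    data generator for heterogeneous-network benchmarks, graph and parameter
    accuracy metrics, file-based workflows and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
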