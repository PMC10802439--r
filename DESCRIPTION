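Package: perturbDiscover
Title: Combinatorial Perturbagen Discovery on Proxy Causal Gene Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the combinatorial set of gene targets whose perturbation
    shifts cells from a diseased to a treated expression state. Couples a
    response-prediction graph neural network with a perturbagen-discovery
    graph neural network trained with a cycle-consistency objective on a
    proxy causal gene-gene network with do-operator edge mutilation. Includes
    a structural-causal-model simulator of disease and treatment intervention
    triplets, graph-corruption procedures (bridge/random edge removal, latent
    confounders), ranking metrics (nDCG, recall at k, percent accurately
    predicted, R squared variants), network-proximity statistics, baselines,
    cross-validation training with independent early stopping, and an
    end-to-end simulate/train/evaluate/benchmark pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Network, GraphAndNetwork, SystemsBiology, GeneExpression
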