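Package: fedgi
Title: Federated Genome Interpretation with Gene-Modular Neural Networks
Version: 0.1.0
Authors@R:
    person("fedgi", "maintainers", email = "fedgi@example.org", role = c("aut", "cre"))
Description: Tools for exome-based case/control risk prediction from
    gene-level mutational-burden encodings, trained under a simulated
    centralized synchronous federated-learning (FL) protocol. Annotated
    variant tables are condensed into per-gene histograms of functional
    variant classes plus two gene-level scores, giving a fixed-shape
    (N, 11, G) feature tensor. A weight-shared gene-modular neural network
    (one shared module applied to every gene, followed by a logistic-like
    read-out) is trained locally with RMSprop, and client updates are merged
    by five server-side aggregation strategies (FedAvg, FedAvgM, FedAdam,
    FedYogi, FedAdagrad). Includes classification metrics with the
    Hanley-McNeil test for comparing AUCs, a synthetic multi-center cohort
    generator with planted gene signal and batch effects, and harnesses for
    leave-one-center-out and federated cross-validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
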