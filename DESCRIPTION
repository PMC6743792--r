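Package: boolpath
Title: Ensemble Boolean Network Propagation, Rule Inference, and
    Topology-Aware Pathway Analysis for Cross-Sectional Transcriptomics
Version: 0.1.0
Authors@R:
    person("Boolpath", "Developers", email = "boolpath@example.org",
           role = c("aut", "cre"))
Description: Models cross-sectional transcriptomic data as ensembles of
    Boolean network trajectories whose initial states are Bernoulli draws
    from max-scaled expression. Infers per-node logic rules (OR-of-ANDs over
    at most three signed regulators) by a genetic algorithm followed by an
    exhaustive node-wise local search that reports equivalent rule sets,
    and scores pathway modulation by in-silico knockout/knock-in impact
    scores with a resampling null. Includes readers for KGML, GraphML and
    SIF networks, a synthetic-network and negative-binomial count
    generator, and drivers reproducing the method's simulation benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
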