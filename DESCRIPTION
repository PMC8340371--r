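Package: dcRWR
Title: Dual-Channel Random Walk with Restart on Signed Heterogeneous Gene Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joins a fully connected gene co-expression network, built from
    single-cell expression counts with the proportionality metric phi_s, to a
    gene-annotation or signed gene-drug bipartite graph, and scores every
    gene-target connection with a dual-channel random walk with restart that
    propagates up- and down-regulation evidence through separate probability
    channels. Per-reference probability vectors are converted to comparable
    scores with a centered log-ratio transform over the target subset.
    Includes in-silico validation protocols (link sparsification rediscovery
    and composite cross-cell-line drug-response imputation), a per-connection
    inter-patient ANOVA with gene-wise false discovery rate control, and a
    synthetic-data generator that plants proportional gene modules, module
    annotations, signed drug responses and patient-specific perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, SingleCell, GeneExpression, Pharmacogenomics
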