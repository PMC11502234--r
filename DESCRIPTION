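Package: dysnet
Title: Transcriptome Dysregulation and Network Topology Analysis
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for bulk RNA-seq dysregulation analysis and downstream
    network biology. Implements a differential-expression chain (CPM with a
    log2 pedestal, cyclic loess cross-sample normalization, covariance-PCA
    outlier flagging, batch correction, noise-floor filtering, and per-gene
    ANCOVA with fold-change calls), weighted gene-coexpression module
    discovery with topological-overlap clustering, a permutation null for
    module-trait correlations, module-membership driver selection and a
    driver-deletion Kolmogorov-Smirnov weight-shift test, protein-interaction
    network construction from STRING-format edge lists with evidence-channel
    rescoring, maximal clique centrality hub ranking, topological
    coefficients, hub-deletion fragmentation statistics, seeded network
    growth, hypergeometric gene-set enrichment, and prepulse-inhibition
    metrics from startle-trial tables. Ships seeded synthetic-data generators
    with ground-truth records for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
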