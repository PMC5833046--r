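Package: placentaScreen
Title: Multi-Stage Screening of Placental Nutrient Transporters in IUGR and
    Pre-Eclampsia
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a multi-stage strategy for
    prioritising placental nutrient transporters (SLC, ABC and TRP family
    genes) altered in intrauterine growth restriction (IUGR) and
    pre-eclampsia (PE). The pipeline covers cross-study differential
    expression meta-screening with vote-count candidate selection, 2^-ddCt
    relative quantification of qPCR data with dual reference-gene
    normalisation and RNA quality filtering, tie-corrected Kruskal-Wallis
    testing with Dunn's post-hoc comparisons, 2D hierarchical clustering
    (centred Pearson correlation, average linkage) with newick and
    clustered-matrix export, Markov clustering of confidence-weighted
    protein-interaction graphs, and a dual-disease log fold-change
    specificity classifier whose intersection with the significant gene set
    yields the final targets. A synthetic-data module generates multi-study
    expression matrices, Ct tables and interaction graphs with planted
    per-gene disease effects so every stage is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Clustering, qPCR,
    GraphAndNetwork, Transcriptomics
RoxygenNote: 7.3.3
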