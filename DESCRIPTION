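Package: csGCN
Title: Condition-Specific Gene Co-Expression Networks with Phased Edge
    Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs condition-specific gene co-expression networks from
    normalized expression matrices. Pairwise gene expression is clustered
    with bivariate Gaussian mixture models so that distinct condition-driven
    modes of co-expression are correlated separately; modes are screened by
    a Fisher-z correlation power filter, tested for association with sample
    conditions by two z-tests of proportions, cleaned of mean-shift-biased
    correlations, and ranked. A two-sample Hotelling T-squared test detects
    "phased" edges, i.e. tissue-specific co-expressed gene pairs whose two
    canopy-position subgroups differ in mean vector while overlapping in
    variance. Edge-based link-community module discovery with McQuitty
    linkage, partition-density dendrogram cuts and meta-module merging, GO
    term enrichment by Fisher's exact test, Boruta all-relevant feature
    selection over random forests, and a seeded synthetic-data generator
    emulating a 2 tissue x 2 position x 4 timepoint x 5 replicate design
    complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, Network, Clustering, GraphAndNetwork,
    FeatureExtraction, GO
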