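Package: screversal
Title: Quantifying Treatment-Induced Reversal of Aging Transcriptomic
    Signatures in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for testing whether a pharmacological treatment
    reverses age-related gene-expression changes across brain cell types in
    single-cell RNA-seq data. Provides a two-part (hurdle) differential
    expression test with likelihood-ratio inference and natural-log fold
    changes, reversal statistics over the union of significant genes
    (proportion of sign-discordant genes and the regression slope of
    treatment fold changes on aging fold changes), selection of top reversed
    genes, binned-control gene-signature module scores with Kruskal-Wallis
    and post hoc Dunn group comparisons, and hypergeometric
    over-representation analysis. Includes a negative-binomial single-cell
    count simulator with planted, recoverable aging and reversal structure,
    readers and writers for MatrixMarket count bundles, typed TSV tables and
    GMT gene-set collections, quality-control filters, normalization,
    high-variance gene selection, PCA, shared-nearest-neighbor graph
    construction and modularity clustering with marker-based cell-type
    assignment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
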