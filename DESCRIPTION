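Package: myoregnet
Title: Integrative Regulatory Genomics of Myometrial Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline linking gene co-expression
    modules in human myometrium to higher-order genome organisation and
    non-coding regulation. Provides negative-binomial synthetic data with
    planted structure (co-expression modules, miRNA-mediated repression,
    domain-localised genes, promoter motifs), log-CPM normalisation and
    moderated two-group differential expression with fold-change/FDR
    filters, co-expression module detection with GSEA-style net enrichment
    scoring, gene-to-TAD localisation statistics with a Kolmogorov-Smirnov
    non-randomness test, JASPAR position-weight-matrix promoter/enhancer
    scanning with exact score-distribution p-values and background-subtracted
    enrichment Z-scores, an integrated miRNA/lncRNA/mRNA/TF correlation
    network with degree/betweenness hub calling, and z-score panel ranking
    of samples along the labour trajectory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
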