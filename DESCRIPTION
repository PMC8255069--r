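Package: coexrules
Title: Co-Expression Modules and Association Rules for Gene Function
    Prediction from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico pipeline for predicting putative functions of
    uncharacterized genes from bulk RNA-seq count matrices. Provides
    negative-binomial count simulation with planted co-expression modules
    and co-regulated gene groups, low-count filtering and median-of-ratios
    normalization, a Welch-test differential-expression screen with
    Benjamini-Hochberg correction, weighted co-expression network analysis
    (soft-threshold adjacency, scale-free fit, topological overlap,
    tree-cut modules, eigengene merging), graph centrality summaries,
    equal-frequency discretization of expression into transactions, a
    from-scratch Apriori miner with support/confidence/lift measures, and
    guilt-by-association annotation of unannotated genes that co-mine with
    annotated chemosensory genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
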