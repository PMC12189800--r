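Package: zganet
Title: Co-Expression Modules and Network Communities for Early Embryo Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative network toolkit for staged embryo transcriptome
    studies such as zygotic genome activation (ZGA) time courses. Provides
    differential-expression threshold filtering and contrast overlaps,
    weighted gene co-expression network analysis (soft-threshold selection,
    topological overlap, module detection, module eigengenes, module-trait
    correlation), hub-core extraction from weighted protein-protein
    interaction networks by degree filtering, a from-scratch weighted
    Louvain community detector with an exhaustive small-graph optimum
    oracle, and hypergeometric over-representation analysis with
    Benjamini-Hochberg correction. A synthetic-data module simulates
    negative-binomial staged counts with planted co-expression modules,
    stochastic-block-model interaction graphs with hubs, and annotation
    sets with planted enrichment, so the full pipeline is testable end to
    end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
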