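Package: gutnet
Title: Gut Microbiota Group Comparisons and Microbe-Based Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for two-group analysis of 16S rRNA taxon count tables and
    for linking a disease's microbiome signature to other diseases. Implements
    exact Wilcoxon rank-sum tests with midrank tie handling and
    Benjamini-Hochberg false discovery rate correction, Greengenes-style
    lineage parsing with rank collapsing, Bacteroidetes/Firmicutes ratios,
    Shannon alpha diversity, Bray-Curtis beta diversity with
    principal-coordinates ordination and a PERMANOVA-style permutation test,
    classification of genera into short-chain-fatty-acid functional groups,
    and construction of signed microbe-based disease similarity networks from
    curated microbe-disease association tables. A Dirichlet-multinomial
    community simulator with planted effects provides ground-truth data for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
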