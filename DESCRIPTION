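Package: shirocore
Title: Cross-Study Integration of Shiro Microbiome Communities by Tree-Based
    Phylotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous amplicon surveys of the Tricholoma
    matsutake mycosphere ("shiro") into comparable taxonomic units and
    analyses them across studies. Provides phylogenetic-tree-based
    phylotyping (single-linkage branch-length clustering with iterative
    monophyly refinement and tree-walking consensus taxonomy), TM-abundance
    soil reclassification via exact univariate k-means, read filtering and
    per-study rarefaction, core-phylotype and consensus niche-specificity
    identification (Kruskal-Wallis/LDA effect sizes, group-equalized
    indicator correlations with permutation nulls, TM co-occurrence),
    Markov clustering of fruitbody co-occurrence networks, and Phenotype
    MicroArray activity scoring. Seeded synthetic-data generators emulate
    the multi-study structure of the real surveys so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
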