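Package: micropart
Title: Abundant/Rare Taxon Partitioning, Assembly Processes and
    Co-Occurrence Networks for Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the community-ecology analysis of amplicon surveys:
    rarefaction and partitioning of OTUs into abundant, moderate and rare
    classes by mean relative abundance; alpha diversity (Chao1, ACE, Shannon,
    Simpson) and Faith's phylogenetic diversity; Bray-Curtis dissimilarity,
    Mantel tests, distance-decay and Levins' niche breadth; phylogenetic-bin
    null-model partitioning of community assembly into heterogeneous and
    homogeneous selection, dispersal limitation, homogenizing dispersal and
    drift via beta-NRI and modified Raup-Crick scores; SparCC compositional
    correlation networks with bootstrap significance, class-aware topology
    summaries and hub detection; and a synthetic-community generator with
    known assembly regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
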