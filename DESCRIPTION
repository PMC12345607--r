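Package: aphidbiome
Title: Simulation and Analysis of Endosymbiont-Dominated Aphid Microbiome
    Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for desk-scale analysis of 16S rRNA amplicon count tables
    from aphid microbiomes dominated by the intracellular endosymbiont
    Buchnera aphidicola. Provides a Monte-Carlo simulator of PCR
    amplification bias across cycles, a synthetic community generator that
    emulates factorial infestation designs (biotype by host cultivar by
    timepoint with replicate plants), contaminant and rare-taxon filtering,
    depth normalization by scaling with ranked subsampling, rarefaction
    curves with exact hypergeometric expectations, alpha diversity (Shannon
    entropy, Hill-1, observed richness), restriction-fraction dominance
    statistics, Jaccard and UniFrac dissimilarities, principal coordinates
    analysis, PERMANOVA with a permutation null, and pathway rank
    comparison between an endosymbiont and the rest of the community.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
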