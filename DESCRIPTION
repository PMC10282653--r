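Package: rad2b
Title: Species-Level Microbiome Profiling from Type IIB Restriction-Site Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reduced-representation microbiome profiling built on type IIB
    restriction endonuclease (BcgI) tags. Performs in-silico digestion of
    reference genomes into iso-length tags, builds a species-unique tag
    database, quality-filters sequencing reads, assigns tags to species with
    a G-score false-positive control, and estimates coverage-normalized
    relative abundances. Downstream analyses cover alpha diversity (Chao1,
    Shannon, Simpson) with Wilcoxon group comparison, beta diversity
    (Bray-Curtis, binary Jaccard, Euclidean) with principal coordinate
    analysis and PERMANOVA, Kruskal-Wallis per-taxon testing, a linear
    discriminant analysis effect-size (LEfSe-style) biomarker screen, and
    random-forest marker selection with probability-of-disease scoring.
    Includes a mock-community simulator that generates reference genomes,
    group-structured compositions and tag-bearing reads with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    randomForest,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
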