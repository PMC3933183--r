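Package: plastidphylo
Title: Plastid Phylogenomic Supermatrices, Compositional Diagnostics and
    Partition-Scheme Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for plastome-scale phylogenomics: single-linkage homolog
    clustering from all-vs-all protein similarity hits, codon-aware
    supermatrix assembly with back-translation and partition bookkeeping,
    character-coding variants (all positions, first+second positions, third
    positions only, RY binary recoding, amino acids), base-composition
    diagnostics (chi-square homogeneity tests, GC versus amino-acid-class
    regressions), a desk-scale partitioned likelihood engine (GTR+G, binary+G,
    empirical amino-acid+G with shared branch lengths) with AICc-based
    comparison of partitioning schemes, taxon-coverage decisiveness analysis,
    majority-rule bootstrap-consensus summaries, and a nonstationary plastome
    sequence simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
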