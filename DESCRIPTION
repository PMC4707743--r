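Package: spongelinc
Title: Discovery and Developmental Expression Analysis of Sponge lincRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying long intergenic
    non-coding RNAs (lincRNAs) from assembled transcriptomes and analysing
    their expression across developmental stages. Transcripts are classified
    into coding, long non-coding and discarded classes by a tiered evidence
    cascade (ORF gating, six-frame translation, homology-hit filters, a
    deterministic coding-potential score); candidates overlapping ORFs or
    introns of coding genes are removed; lincRNAs co-expressed with their
    nearest coding neighbour are filtered out; stage-upregulated lincRNAs are
    detected with a negative-binomial Wald test; and co-expressed
    lincRNA/coding-gene modules are found via topological-overlap clustering
    with a dynamic tree cut. A synthetic-data generator with full planted
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
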