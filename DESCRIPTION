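Package: npvanno
Title: Annotation and Comparative Genomics of Nucleopolyhedrovirus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating large circular double-stranded DNA virus
    genomes in the style used for alphabaculoviruses: six-frame open reading
    frame (ORF) calling on circular sequences with length/overlap filter rules,
    detection of homologous regions (hrs) as clusters of near-identical
    palindromic repeat units with consensus and per-position base-frequency
    profiles, classification of early/late promoter motifs upstream of start
    codons, classification of intra-isolate sequence variants, Kimura
    2-parameter nucleotide distances (with optional gamma rate correction) and
    a species-demarcation verdict, gene-parity synteny plots with inversion
    detection, and neighbor-joining phylogenies from maximum-likelihood
    amino-acid distances under empirical substitution models with bootstrap
    support. A seeded synthetic-genome simulator generates genomes, variant
    tables and alignments with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
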