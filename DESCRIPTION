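Package: baculoscan
Title: Annotation and Comparative Analysis of Circular Baculovirus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational workflow used to
    characterize a nucleopolyhedrovirus genome: six-frame ORF discovery on
    circular genomes under a liberal (<50 percent) overlap criterion, direct-repeat
    and homologous-region (hr) detection with core-motif counting, synonymous
    versus non-synonymous classification of intrapopulation single nucleotide
    variants, Kimura 2-parameter distances on marker genes with the
    alphabaculovirus species-demarcation rule, reciprocal-best-hit orthology
    with pan-genome Venn partitioning and anchored locus-context extraction,
    and a seeded synthetic-genome generator so the full pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
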