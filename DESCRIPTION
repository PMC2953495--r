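Package: conjoinr
Title: Detection and Characterization of Conjoined (Read-Through) Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies conjoined genes (CGs) - transcripts that combine at
    least part of one exon from each of two or more distinct same-strand
    parent genes - from spliced mRNA/EST alignments against a gene
    annotation, then characterizes them: automated curation of paralog,
    unspliced and short-alignment false positives, locus collapse of
    single-locus naming variants, splicing-pattern classification
    (junction-intron pattern, novel exons, conserved vs new splice sites,
    GT-AG canonicality), ORF prediction with per-parent reading-frame
    comparison and nonsense-mediated-decay candidacy, junction-exon
    extraction with short-homologous-sequence detection and a
    seed-and-extend cross-species conservation search, and enumeration of
    potential CG-forming gene pairs. A deterministic simulator generates
    toy genomes with planted CGs of every class plus labelled negatives so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
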