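Package: intronspan
Title: Cross-Species Intron-Spanning Genic PCR Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs cross-species genic PCR markers from pairs of orthologous
    genes. Exon-intron junctions are located by spliced anchoring of a coding
    sequence onto its genomic locus, the two species' coding sequences are
    globally aligned, and conserved gapless exonic blocks become templates for
    intron-spanning primer pairs that are scored, ranked and refined. Virtual
    (electronic) PCR maps candidate primers onto whole genomes with bounded
    mismatches to classify amplification specificity, and a downstream module
    calls SNPs between parental amplicons and screens restriction enzymes for
    cleaved amplified polymorphic sequence (CAPS) markers. A seeded simulator
    of ortholog gene pairs, multi-gene genomes and paralog copies provides a
    fully reproducible test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
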