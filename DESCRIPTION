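Package: annotrack
Title: Tracking Gene, Protein and SNP Annotation Across Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares gene annotation between two assemblies of the same
    genome. Maps spliced transcript sequences onto a target assembly with a
    two-stage seeded aligner, classifies exon-intron structure compatibility
    between mapped transcripts and the local annotation, classifies
    differences between conceptual protein translations and their reference
    models, and remaps SNP flanking-context sequences with a found/mapped
    two-tier filter. Includes a synthetic dual-assembly simulator that plants
    multi-exon genes and SNPs in a source genome and derives a second
    assembly carrying labelled mis-assembly events (inversions,
    translocations, gaps, duplications, unplaced segments, substitution
    noise, frameshifting indels) so that every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
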