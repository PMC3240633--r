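Package: iscmscan
Title: Stop Codon Mutation Annotation and Multi-Strain Comparison for
    Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Strand-aware annotation of single-nucleotide variants against
    single-exon ORFs in compact fungal genomes, with emphasis on
    inactivating stop codon mutations (ISCMs): premature stop detection,
    truncation-length and mutation-notation conventions, stop-loss
    scanning, per-strain summaries, ORF-by-strain ISCM presence/absence
    matrices, neighbor-joining strain phylogenies from SNP differences,
    and exact-clade attribution of strain- and lineage-unique variants to
    tree branches. Includes a seeded simulator that plants variants of
    known consequence on known branches so every stage is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    vcfR,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
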