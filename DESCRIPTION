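Package: alloexpr
Title: Additivity, Expression-Level Dominance and Homoeolog Bias in
    Allopolyploid RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of gene expression in interspecific hybrids and
    allopolyploids from paired-end RNA-seq fragment counts. Implements
    paired-read acceptance counting against a concatenated two-subgenome
    reference, FPKM quantification, per-gene Fisher's exact differential
    tests with Benjamini-Hochberg correction, mid-parent-value additivity
    testing, classification of each gene into 19 expression patterns and 9
    expression categories, extraction of the four forms of expression-level
    dominance and of transgressive expression, and classification of
    homoeologous gene pairs into nine expression-bias categories with
    parental-legacy accounting. Includes a negative-binomial count
    simulator with per-gene truth labels so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
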