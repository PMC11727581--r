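Package: retronet
Title: Retrotransposon Discovery from Pairwise Genome Alignment Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects retrotransposition events ("copy and paste" insertions
    flanked by target-site duplications and poly(A) tails) from UCSC net-format
    pairwise whole-genome alignments.  Gap-enclosed fill regions of the net
    hierarchy are scanned for flanking target-site duplications (banded
    ungapped alignment) and adjacent poly(A) runs on both strands, scored, and
    filtered.  Includes a target-primed reverse transcription insertion
    simulator with emulated net output and ROC/AUC benchmarking, genomic
    category and L1-endonuclease motif (TTAAAA) annotation, and expression
    utilities (RPM normalisation, expressed-copy filtering, Tau tissue
    specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
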