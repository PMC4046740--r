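Package: strandtag
Title: Tag-Based Strand-Specific RNA-Seq Read Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and removal of a 12-nt strand tag from sequencing
    reads with single-variation (edit distance <= 1) tolerance, splitting of
    concatenamer-derived reads at ligation junctions, chimera and orientation
    classification, a 454/Illumina-like read simulator with planted ground
    truth, simulation-based accuracy scoring, tag-driven transcript-strand and
    antisense assignment of aligned reads, and k-mer rarity scoring for tag
    design against a transcriptome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
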