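Package: anemone
Title: Post-Assembly Analysis of a Clonal Diploid Transcriptome
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-assembly computations for a de novo transcriptome of a
    clonal diploid animal: quality trimming and duplicate-read collapsing,
    detection and repair of palindromic (hairpin) mis-assembled contigs,
    read-to-contig block alignments with validity filtering, pileup
    construction, threshold-based heterozygous SNV and indel calling with a
    transition/transversion spectrum summary, modal-coverage genome-size
    estimation, paired-end orientation concordance validation, assembly
    summary statistics, and a grammar-based scanner for GLW-amide
    neuropeptide precursors. Includes a synthetic diploid-transcriptome
    generator with planted-variant truth tables so every stage can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
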