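Package: mitescope
Title: MITE Annotation, Simulation and Comparative Analysis for Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of miniature inverted-repeat
    transposable elements (MITEs). Provides a synthetic allopolyploid genome
    simulator with planted insertions and ground truth, homology-based
    retrieval of MITE copies with flank capture and deduplication, structural
    characterization (terminal inverted repeats, target site duplications,
    sequence logos, haplotype diversity, consensus building), de novo
    discovery of TIR/TSD-bounded families, genomic-context annotation with a
    100-bp gene-association rule, and comparative tabulation of insertions
    across sub-genomes including cross-ploidy common-insertion analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
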