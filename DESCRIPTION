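Package: clipcall
Title: Structural Variant Discovery from Clipped Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects structural variants (deletions, insertions, inversions
    and translocations) from paired-end short-read alignments. Soft-clipped
    reads are extended into longer sequences by head-to-tail overlap,
    realigned with a spliced (large-gap) aligner, and deletions and short
    insertions are read off the resulting CIGAR strings. Insertion
    candidates that resist spliced alignment are resolved through a
    sequence of decision rules: alignment CIGAR, spliced alignment, local
    de Bruijn assembly and complex read alignment. The package also ships a
    diploid spike-in genome and paired-end read simulator and a
    benchmarking module that matches calls against a truth set with
    windowed breakpoint and size criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    parallel,
    stats,
    tools,
    utils
Suggests:
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
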