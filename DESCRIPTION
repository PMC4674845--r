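Package: clipjunc
Title: Classification-Based Splice Junction Calling from Clipped RNA-seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls splice junctions from clip-reporting DNA alignments of
    paired-end RNA-seq reads (e.g. BWA output). Candidate donor/acceptor
    sites are detected from soft/hard-clip positions and coverage-change
    points, described by four coverage-normalized evidence features (clipped
    reads, re-aligned clipped segments, discordant encompassing pairs,
    coverage difference), classified with a support vector machine trained on
    simulation truth or annotation, and assembled into junctions by focal
    mate-bounded re-alignment of clipped segments with an insert-size
    conflict filter. Includes a paired-end spliced-read simulator with an
    aligner emulator and truth sets, plus slack-based benchmarking utilities
    (precision/recall/F-value, call-set overlap, mapped-base ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rsamtools,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
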