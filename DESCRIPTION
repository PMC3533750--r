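Package: spliceArray
Title: Virtual Microarray Profiling of Splice Junctions from Short RNA Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a non-redundant, annotated database of splice-junction
    events from transcript-to-genome alignments, turns each event into a
    fixed-length junction-spanning probe (a "virtual microarray"), maps short
    RNA reads onto the probes under a Hamming mismatch budget keeping only
    unique junction-spanning hits, normalizes per-event counts to RPKM across
    samples, and calls condition-specific differential splice events in
    matched designs with a gene-expression confound filter and hierarchical
    clustering of sample signatures. Includes a multi-isoform read simulator
    with planted differential splicing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
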