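Package: cracpause
Title: RNA Polymerase Pausing Analysis from CRAC 3'-End Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify RNA polymerase I pausing along an rDNA
    transcription unit from CRAC/NET-seq style nascent-transcript data.
    Read 3' ends mark the polymerase active site; the package counts them
    per nucleotide, converts counts to pseudocounted read fractions,
    smooths tracks with a Blackman window, aggregates biological
    replicates (median with a Q2-Q3 band), forms log2 depleted/wild-type
    ratio tracks, converts fractions to per-position occupancy times via
    the unit length and mean elongation velocity, and calls pause sites
    as prominent local maxima. A stochastic elongation simulator with
    known per-position dwell times generates synthetic read sets so every
    stage is testable without external data, and ChIP-qPCR (2^dCT) and
    RT-qPCR (ddCq) helpers cover the accompanying quantification
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
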