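Package: tfloops
Title: Transcription-Factor Co-Binding and 3D Chromatin Structure Statistics
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit linking transcription-factor co-binding to
    three-dimensional chromatin architecture. Provides permutation and
    hypergeometric tests for ChIP-seq peak co-occurrence over an
    open-chromatin universe, a distance-decay background model for binned
    cis contact maps with cumulative-binomial interaction (loop) calling,
    differential interaction scoring between conditions, loop-anchor
    feature-pair enrichment, directionality-index domain (TAD) calling with
    boundary-relative metagene profiling, knockdown response classification
    of per-peak tag counts, and differential-expression gene-set
    intersection. A synthetic-data module generates peak sets, gene tables,
    contact read pairs and contrast tables with planted ground truth so the
    whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
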