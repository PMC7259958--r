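Package: circlecall
Title: Transcript-Error Identification from Rolling-Circle Consensus Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcription errors from rolling-circle (CirSeq-style)
    sequencing of circularized RNA fragments. Reads containing tandem repeats of
    the same template are collapsed into consensus fragments by autocorrelation
    period detection and Bayesian consensus calling with recomputed per-base
    posterior error probabilities; ligation junctions are recovered by mapping a
    tandem duplicate of each consensus back to the reference; per-site pileups
    are filtered (posterior threshold, repeat count, end trimming, site-frequency
    and ncRNA-paralog filters) into substitution and indel error calls. Downstream
    statistics cover conditional substitution spectra, codon-usage-based expected
    effect percentages, per-gene Poisson enrichment, transition-bias tests, and the
    positional analysis of nonsense errors along mRNAs with weighted linear
    regression. A seeded simulator of annotated genomes and rolling-circle reads
    with planted transcript, reverse-transcription, and sequencing errors makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
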