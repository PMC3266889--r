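Package: poolte
Title: Transposable Element Insertion Calling and Population Frequency
    Estimation from Pooled Paired-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transposable element (TE) insertions, both present in and
    absent from a reference genome, from paired-end reads of a pooled
    population sample (Pool-Seq). Paired-end fragments with one read anchored
    in the unique genome and the mate in a TE sequence are clustered into
    directional insertion signals, forward and reverse signals are joined with
    repeat-mask-aware distances, and per-insertion population frequencies are
    estimated from presence/absence fragment tallies in 100 bp ranges so that
    insertions known from the reference and novel insertions are treated
    identically. Includes a binomial detection model for the number of
    reference insertions missed by detection, a windowed Tajima's D scan of
    subsampled pileups for candidate positively selected insertions, and a
    seeded simulator of pooled samples for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
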