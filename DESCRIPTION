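Package: poremod
Title: Detection of RNA Modifications from Nanopore Direct RNA Sequencing
    Error and Signal Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting chemically modified positions in direct RNA
    nanopore sequencing data from synthetic standards. Implements per-position
    basecall pileup error profiling (total variation percentage and its
    mismatch/deletion/insertion breakdown), a multivariate two-sample energy
    distance computed over sliding 3-nt windows of per-read signal features
    (log dwell time, current mean, current standard deviation), site-level
    detection benchmarking (AUROC, AUPRC, thresholded confusion matrices,
    proximity attribution of false positives), summarization of
    modification-aware basecaller pileups (bedMethyl-like), and a seeded
    synthetic-data generator emulating the error and signal phenomenology of
    modified RNA standards so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
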