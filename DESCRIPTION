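Package: echopool
Title: ERCC Spike-In QC and Two-Step Library Pooling for Miniaturized mNGS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational layer for miniaturized, acoustic-dispenser based
    metagenomic next-generation sequencing (mNGS) library preparation in
    384-well format. Provides ERCC spike-in quality control (dose-response
    fitting across the 92-species concentration ladder) and back-calculation
    of input RNA mass from spike-in read share; a two-step library pooling
    planner (equal-volume pilot pool, read-fraction estimation, inverse
    fraction equimolar re-pool) under acoustic-dispenser volume constraints,
    with predicted read distributions and a variance-ratio F test; pathogen
    and transcriptome detection metrics (reads per million, hypergeometric
    downsampling, coverage breadth and depth, Spearman rank correlation);
    and a seeded synthetic-data generator so the whole pipeline is testable
    on multinomially sampled count data without sequencer output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
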