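Package: cleaverate
Title: Endoribonuclease Cleavage-Site Detection and Transcript Decay
    Kinetics from RNA-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects RNase III cleavage sites in bacterial transcriptomes by
    comparing per-base RNA-seq coverage between a wild-type strain and an
    RNase-deletion mutant (pseudocounted mutant/wild-type coverage ratios,
    dual-replicate thresholding, minimum-spacing site selection), and
    quantifies transcript decay from rifampin-chase time courses
    (stable-gene normalization, log10-linear least-squares fits of
    A = 10^(-kt) with coverage and R-squared gates, half-lives
    t1/2 = log10(2)/k, and wild-type versus mutant stability contrasts).
    Includes readers and writers for bedGraph, fixed-step wiggle, BED and
    GFF3, a seeded synthetic time-course generator with planted cleavage
    sites and known half-lives for end-to-end validation, and a
    reproducible pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
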