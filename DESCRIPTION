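Package: triadheterosis
Title: Triad Transcriptome and Trait Analysis of Biomass Heterosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of F1-hybrid versus parent ("triad") RNA-seq experiments
    for the study of heterosis (hybrid vigor). Provides negative-binomial Wald
    tests for the three triad contrasts with median-of-ratios normalization,
    classification of differentially expressed genes into the twelve
    additive/dominant/overdominant expression patterns, hypergeometric
    over-representation analysis with Benjamini-Hochberg correction,
    mid-parent heterosis statistics for trait time courses with Duncan
    multiple-range-test letter groupings, 2^-ddCt qPCR relative
    quantification with RNA-seq concordance checks, a seeded synthetic-data
    generator with known pattern labels, and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2,
    yaml,
    optparse
Config/testthat/edition: 3
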