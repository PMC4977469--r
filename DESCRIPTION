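Package: mesopotency
Title: Culture-Condition Comparison of Stem-Cell Transcriptome, Methylome and
    Signaling Propensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for comparing human embryonic stem cell cultures
    grown under different conditions: rank-product differential expression and
    methylation with permutation-based proportion-of-false-positives estimates,
    regulation-dynamics classification and dot-product K-means clustering of
    fold-change profiles, EASE-score (deflated hypergeometric) enrichment
    against annotation and transcription-factor target sets with window-based
    target assignment, paired gene-set tests, expression-methylation
    association, signed signaling-cascade propensity scoring, and qPCR
    delta-delta-Ct induction analysis with one-tailed induction-outcome
    correlation. Includes a seeded synthetic-data generator with planted
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
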