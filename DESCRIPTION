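Package: tdnovelty
Title: Temporal Novelty Scoring for Target-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs the yearly evolution of target-disease association
    scores from timestamped evidence records using the harmonic-sum scoring
    framework of the Open Targets Platform, and quantifies moments of
    biomedical novelty with a logistic-decay metric applied to year-over-year
    score shifts. Includes peak detection, cutoff-based novelty
    classification, a retrospective analysis of novelty peaks against drug
    approval years, a seeded synthetic evidence-corpus generator for
    validation, and readers and writers for JSON-lines and tab-delimited
    evidence and approval tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
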