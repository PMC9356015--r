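Package: degmods
Title: Cross-Species DEG Overlap and Protein-Interaction Module Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for microdeletion transcriptomes: count
    filtering and differentially-expressed-gene (DEG) selection with
    Benjamini-Hochberg correction, ortholog-mapped cross-species DEG
    overlap with a Monte-Carlo permutation null, extraction of
    DEG-interacted functional modules from a protein-interaction network
    using experimentally supported GO biological-process annotations, a
    running-sum enrichment-score statistic with permutation z-scores to
    classify modules as activated or inactivated, deletion-region dosage
    checks, developmental-stage expression filtering with Tukey HSD
    profile tests, and binomial enrichment against neurodevelopmental
    disorder gene lists. Includes a synthetic-data generator with planted
    ground truth so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
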