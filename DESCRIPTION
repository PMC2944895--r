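Package: hcscreen
Title: Multi-Parameter High-Content Screening Statistics with B-Score
    Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics pipeline for multi-parameter high-content
    screens in multiwell plates: per-well summarization of per-cell
    fluorescence measurements (median and upper-quantile statistics),
    per-plate B-score normalization by Tukey two-way median polish with
    missing-well support, replicate aggregation, cytotoxicity exclusion,
    hit calling by a median +/- 2*MAD band with an SEM non-overlap rule,
    Kruskal-Wallis row/column bias diagnostics, and a seeded synthetic
    screen generator with ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'wells.R'
    'io.R'
    'summarize.R'
    'plate-matrix.R'
    'medpolish.R'
    'hits.R'
    'bias.R'
    'simulate.R'
    'pipeline.R'
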