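Package: dubscreen
Title: Deubiquitinase Substrate Screening from Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative identification of deubiquitinating-enzyme (DUB)
    substrates from biotin pull-down label-free proteomics. Reads
    MaxQuant-dialect protein-group and GlyGly-site tables, applies decoy /
    contaminant / identified-by-site row filters, imputes left-censored
    missing values from a downshifted normal distribution, tests
    differential ubiquitination between control and DUB-silenced samples
    with two-tailed Student's t-tests, and calls putative substrates with a
    three-criterion rule (fold change, unique peptides, imputation counts).
    Includes quality-control diagnostics on endogenously biotinylated
    carboxylases and ubiquitin, replicate Pearson correlation and overlap
    counts, a queryable threshold-adjustable substrate store, and a
    synthetic-data generator with ground truth for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
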