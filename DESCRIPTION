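Package: smstruct
Title: Single-Molecule RNA Structure Probing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-molecule RNA structure probing with
    nanopore sequencing. Calls chemical modifications on individual reads from
    per-base statistics with an FDR-calibrated threshold, quantifies base-pair
    co-dependencies with distance-normalized adjusted mutual information
    (dAMI), co-openness and co-agreement, resolves structural heterogeneity by
    hard-constrained folding and read-to-structure clustering with a
    permutation null, computes stratified differential accessibility
    (Cochran-Mantel-Haenszel) and transcriptome-level structural feature
    profiles, and ships a seeded ensemble simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
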