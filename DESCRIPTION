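Package: mirsets
Title: Enrichment Analysis of MicroRNA Regulator Sets for Protein-Coding Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers patterns of protein-coding genes from the microRNAs
    predicted to regulate them. For a single gene, a gene list, or a
    pathway, the package collects the predicted miRNA regulators from a
    target-prediction table and tests each predefined miRNA set (genomic
    cluster, sequence family, curated function, associated disease,
    tissue specificity) for over-representation among those regulators
    with the one-sided hypergeometric test, reporting count, percent,
    fold enrichment, and raw, Bonferroni- and Benjamini-Hochberg-adjusted
    p-values. Includes a seedable synthetic-resource generator with
    planted enrichments so the whole pipeline is testable offline, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
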