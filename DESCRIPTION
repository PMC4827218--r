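Package: mbsubtyper
Title: Single-Sample Medulloblastoma Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individual gene-expression profiles from human or
    mouse medulloblastoma samples into the consensus molecular subtypes
    (WNT, SHH, Group3, Group4) or Normal. Enrichment of Gene Ontology
    Biological Process gene sets is scored per sample with single-sample
    gene set enrichment analysis (ssGSEA), gene sets are harmonized across
    species through a shared term namespace, per-sample gene-set rankings
    form the feature space, and a k-nearest-neighbour vote against a
    labelled reference cohort yields a subtype call with a vote-fraction
    confidence. Includes readers and writers for GMT, expression, label and
    prediction tables, a trainable reference model, a synthetic cohort
    generator for testing, and ggplot2 visualisations of predictions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
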