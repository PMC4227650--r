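Package: promscreen
Title: Selection of Stress-Inducible Promoters from Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens normalized gene-expression compendia for strongly
    stress-inducible genes whose promoters can drive phytotoxic transgene
    expression in plant biofactories. Implements threshold-based induction
    screening (difference and absolute-level filters with probe-to-gene
    collapse), basal-activity profiling across transformation-relevant
    tissue panels, classification of candidates against empirically
    anchored expression thresholds, cross-stress specificity checks, and
    hierarchical clustering of candidate profiles. Bundles the supporting
    quantitative validation statistics (efficiency-corrected qPCR relative
    expression, geNORM reference-gene stability M values, transgene
    copy-number calls, normalized transformation efficiency with a
    workability rule) and a fully deterministic synthetic-compendium
    generator with planted ground truth so every stage is testable without
    external data.
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
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
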