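Package: gipairs
Title: Genetic Interaction Scoring for Combinatorial CRISPR Double-Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores genetic interactions (synthetic lethality and synthetic
    viability) from pooled combinatorial CRISPR double-knockout screens. Guide-pair
    read counts are normalized to the plasmid input and anchored on double
    olfactory-receptor control constructs; per-guide single-knockout effects
    estimated from OR pairings define an additive expected double-knockout effect,
    and the difference dLFC between observed and expected log2 fold change is
    tested per gene pair with paired t-tests and a two-stage step-up false
    discovery rate adjustment. Post-hoc saturation, time-course and essential-gene
    filters, multi-screen network fusion, condition-rewiring comparison, and a
    generative screen simulator with known ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
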