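Package: beditlib
Title: Library-Scale Analysis of CRISPR Base-Editing Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying base-editing outcomes in genomically
    integrated paired sgRNA/target-site libraries. Implements the full
    read-processing chain (quality filtering, tiled 6-mer locality-sensitive
    candidate nomination, spacer-match filtering and Needleman-Wunsch
    genotyping restricted to the tracked substitution classes), replicate-aware
    binomial noise filtering, batch-effect screening, editing-window and
    selectivity statistics, sequence-context motif learning by ridge
    regression on stabilized-logit efficiencies, and editor-to-editor
    comparison by total least squares. A synthetic comprehensive-context
    library generator with a parameterized editor model makes every stage
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
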