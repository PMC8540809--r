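Package: nafcflow
Title: Linking Microbial Transcriptomes to Naphthenic Acid Fraction Compound Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow connecting the transcriptomic responses of
    oil-sands Pseudomonas cultures to the chemistry of naphthenic acid
    fraction compounds (NAFCs). Provides molecular-formula parsing,
    double-bond-equivalent computation and heteroatom classing for
    Orbitrap-derived feature tables; coverage-filtered TPM expression
    summaries with MA (log-ratio / mean-intensity) statistics and KEGG-style
    pathway ranking; EC-number consolidation across annotation sources with
    hypergeometric over-representation analysis; EC-to-substrate matching
    against local reaction, compound and pathway databases with chi-square
    comparison of substrate class distributions and pathway presence
    inference; and a seeded synthetic-fixture generator with a planted-truth
    manifest so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    stats,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
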