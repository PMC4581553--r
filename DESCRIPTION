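Package: midparent
Title: Gene-Action Classification and Midparent Heterosis from Three-Library RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of interspecific-hybrid transcriptomes from three
    sequencing libraries (two parents and their F1 hybrid) without biological
    replicates. Implements RPKM quantification, expressed-gene calling and the
    seven-region Venn partition of expressed sets, the Audic-Claverie exact
    test for count differences between libraries with Benjamini-Hochberg
    correction, classification of differentially expressed genes into
    gene-action modes (additivity, high- and low-parent dominance, over- and
    underdominance, partial dominance) against the midparent reference,
    midparent heterosis values, hypergeometric enrichment scans over
    chromosomes, subgenomes and GO terms, transposable-element activation
    calls, 2^-ddCt qPCR fold changes with direction concordance, and a
    synthetic three-library count generator with a known truth table for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
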