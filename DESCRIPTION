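Package: epibuffer
Title: Quantitative Analysis of Genetic Buffering and Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ratio-scale framework for classifying, quantifying, and
    comparing buffering relationships between genes. Provides the algebra of
    the five buffering parameters (transfer fraction, buffer fraction, the two
    compartment ratios, and the buffering angle), serial and parallel
    neutrality models for expected double-mutant fitness under linear,
    quadratic, and exponential growth, epsilon interaction scales with
    landmark values and epistasis classification, a residual-analysis pipeline
    for synthetic genetic array (SGA) cross tables (expectations, q-values,
    filters, standardized residuals, hybrid model selection, two-sample
    Cramer-von Mises comparisons), a generator of synthetic SGA-like data with
    known ground truth, and gene-interaction diagrams exportable as DOT or
    JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
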