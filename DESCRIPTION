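Package: mirlink
Title: Integrative mRNA/miRNA Differential Expression, Consensus Target
    Prediction and Inverse-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-group microarray-style
    transcriptomic studies that profile both mRNAs and microRNAs, modelled
    on developmental comparisons of muscular-type arteries. Provides
    quantile normalization, per-feature one-way ANOVA with
    Benjamini-Hochberg correction and fold-change filters, multi-algorithm
    consensus filtering of predicted miRNA-target interactions with hub
    classification, Fisher's exact overrepresentation of pathways and
    miRNA binding sites, and the inverse-expression integration of the two
    layers (up-regulated genes against down-regulated miRNAs and vice
    versa). Includes a seeded synthetic-data generator with planted
    negative miRNA-to-gene regulation so every stage is testable against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
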