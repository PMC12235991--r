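Package: paralogLR
Title: Paralogous Pathogenic Variants as Calibrated Evidence for Missense
    Variant Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates missense variants with pathogenic variants found at
    corresponding multiple-sequence-alignment positions in paralogous genes
    (the para-SAME and para-DIFF criteria), calibrates that evidence as
    positive likelihood ratios with confidence intervals (pooled, gene-wise,
    conservation-stratified and region-restricted), correlates phenotypes by
    the 3D positions of their variants on a reference protein structure
    using Kendall rank correlation, and evaluates phenotype-informed
    evidence selection by four-fold cross-validation. Includes seeded
    synthetic-data generators with analytic ground truth so the full
    pipeline is testable without external variant databases, and a
    command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
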