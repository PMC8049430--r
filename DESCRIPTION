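Package: entroseq
Title: Entropy-Based Condition-Specificity Scoring for RNA-Seq Count Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores per-gene expression variability across many growth or
    developmental conditions from gene-level RNA-seq count tables. Counts are
    normalized to transcripts per million (TPM), each gene's cross-condition
    expression profile is reduced to a fraction vector, and an entropy-based
    specificity score (the Kullback-Leibler divergence from the uniform
    profile, in bits) classifies genes as constitutive-like or
    condition-specific. Includes readers and writers for featureCounts-style
    tables, condition metadata and gene-set lists, gene-set benchmarking via
    kernel density estimates and entropy-ranked log2-TPM heatmaps, a
    negative-binomial synthetic count-matrix generator with known per-gene
    classes for validation, and pipeline drivers with a thin command-line
    wrapper.
License: MIT + file LICENSE
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    scater,
    SingleCellExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
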