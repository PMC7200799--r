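Package: vascaging
Title: Single-Cell Transcriptomics of Arterial Aging: UMI Processing,
    Transcriptional Noise and Master-Regulator Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational chain used in single-cell studies of
    primate arterial aging: STRT-style barcoded UMI read parsing and
    collapsing into count matrices, cell- and gene-level quality filters,
    log-normalization and dispersion-based highly-variable-gene selection,
    old-versus-young Wilcoxon differential expression with Bonferroni
    correction, an ERCC-calibrated per-cell transcriptional-noise statistic
    (biological Euclidean distance over spike-in technical distance), and a
    simplified master-regulator analysis that infers TF-target edges, scores
    regulon activity against the aging signature and ranks regulatory hubs.
    Includes a negative-binomial synthetic-data generator that plants known
    age effects (differential genes, noise inflation, a coherently
    downregulated hub TF regulon) with full ground-truth labels, so every
    stage can be validated by truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
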