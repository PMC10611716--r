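Package: qgikit
Title: Quantitative Genetic Interaction Scoring for Pooled CRISPR Screens
    with N-Terminal Acetylome and Differential Abundance Companions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for scoring quantitative genetic
    interactions (qGI) from pooled genome-wide CRISPR knockout screens:
    counts-per-million normalization, T0 abundance filtering, replicate-averaged
    guide-level log2 fold-changes, residuals against a wild-type control panel
    with LOESS and T0-dependence corrections, empirical-Bayes moderated
    t-statistics with Benjamini-Hochberg correction, and a within-vs-between
    replicate correlation (WBC) reproducibility z-score. Companion modules
    quantify N-terminal acetylation degrees from Ac/AcDC peptide ratios with
    NAT-type substrate classification, and perform Perseus-style differential
    protein abundance testing (valid-value filtering, downshifted-normal
    imputation, S0-moderated t/F statistics, BH or permutation-based FDR).
    Seeded simulators generate screen counts, N-terminal peptide tables and
    label-free quantification matrices with known ground truth for every stage.
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
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
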