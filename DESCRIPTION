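Package: phosbench
Title: Benchmarking Pairwise Association Measures for Phosphoproteomics
    Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how well pairwise association measures
    recover kinase-substrate and substrate-substrate signalling networks
    from mass-spectrometry phosphoproteomics matrices. Provides a
    linear-Gaussian vector-autoregressive simulator over the Raf pathway,
    six association measures (Pearson, Spearman and Kendall correlation,
    plug-in mutual information on optimally discretized data, the
    directional functional chi-squared statistic, and shrinkage Gaussian
    graphical model partial correlations), construction of gold-standard
    label matrices from phosphosite-resolved interactomes with optional
    machine-learning augmentation, regulation filters and normalizations
    for time-series and perturbation designs, a BLOSUM62 local-alignment
    peptide-similarity filter with dataset-specific thresholds,
    AUROC/precision-recall/Fisher evaluation with permutation nulls, and
    a fully synthetic phosphoproteome generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
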