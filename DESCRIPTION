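Package: capen
Title: Cross Approximate Entropy Connectivity Analysis for EEG Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear EEG functional connectivity analysis built around cross
    approximate entropy (C-ApEn), a delay-embedding statistic of the asynchrony
    between two time series. Implements the fixed 10-site speech-articulation
    montage of the international 10-20 system (bilateral DLPFC, IFG, M1, SPT,
    IPL) with its 21 intra- and inter-hemispheric electrode pairs, a
    preprocessing/epoching/artifact-rejection pipeline producing per-subject
    task-minus-rest difference values and pre/post change scores, a seeded
    coupled-latent-source simulator for two-arm pre/post trial datasets with
    clinical covariates and speech scores, and the full trial statistics layer:
    normality-routed two-group and paired comparisons, pooled-SD standardized
    effect sizes, Pearson chi-square on contingency counts, univariate screening
    with multivariate linear regression, and paired-design power via the
    noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
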