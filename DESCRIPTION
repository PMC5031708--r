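Package: fnirsGCA
Title: Granger Causal Effective Connectivity Networks for Developmental fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise Granger causality mapping of multichannel fNIRS
    oxy-hemoglobin time series and group-level inference on the resulting
    directed networks. Implements the canonical preprocessing chain
    (HRF-shaped low-pass smoothing, drift removal, two-point baseline
    correction), bivariate vector-autoregressive Granger causality with
    BIC order selection, per-edge repeated-measures ANOVA (two-level
    within-participant condition by continuous age) with subsample-averaged
    partial eta-squared effect sizes tested against a condition-scramble
    permutation null, neural other-race-effect (NORE) age correlations,
    and directed-network assembly with anatomical edge classification.
    Includes a synthetic cohort generator that plants known age- and
    condition-dependent causal couplings so the full pipeline is testable
    end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
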