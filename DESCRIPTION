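Package: hrvalid
Title: Validation of Wearable Heart-Rate Monitors Under Dynamic Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for method-comparison studies of wearable heart-rate
    monitors against a reference device over a phased activity protocol.
    Simulates reference and device heart-rate streams with configurable
    observation models (reporting schedule, lag, bias, motion-inflated
    noise, dropout), builds paired datasets at per-second, trailing 10 s
    and synchronized 60 s resolutions with pairwise deletion, segments
    transient versus steady states around protocol phase changes, and
    computes per-participant accuracy (MAE, MAPE), repeated-measures
    concordance and correlation, mixed-model Bland-Altman limits of
    agreement, and paired Wilcoxon device comparisons with Bonferroni
    control, with report and figure generation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    lme4,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
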