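Package: vkproteome
Title: Mixed-Model Association Analysis of the Plasma Proteome and Vitamin K Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nutriproteomic association studies that combine
    multiplexed isobaric-label (iTRAQ) proteomics experiments with a plasma
    nutritional biomarker. Provides per-channel median normalization of log2
    reporter-ion intensities, a random-intercept linear mixed model estimated
    by restricted maximum likelihood (REML) with experiment-level random
    effects, percent-change effect estimates per doubling of protein
    abundance, Storey q-value false discovery rate estimation,
    deficiency-group differential abundance, within-experiment-averaged
    protein correlation networks, and a calibrated synthetic-cohort generator
    emulating a 500-child, 72-experiment study of PIVKA-II (subclinical
    vitamin K deficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    lme4,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
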