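Package: sinkcf
Title: Confidence-Gated Hybrid Inference of the Underlying Cause of Death
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automatic inference of the underlying cause of death from
    death-certificate cause-of-death chains coded in ICD-10. Implements
    conditional death-cause proportion (CDCP) statistics stratified by age
    group and gender, the sink strategy with a trigonometric confidence
    gate, and a CDCP-weighted Jaccard collaborative-filtering fallback over
    a library of adjudicated historical cases. Includes k-fold
    cross-validation with per-cause F1 reporting, a seedable synthetic
    mortality-registry generator with analytic oracles for parameter
    recovery, and a command-line interface for training, prediction,
    evaluation and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
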