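Package: dsfuse
Title: Deviation-Support Fuzzy Fusion of Classifier Probabilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-level fusion of class-probability outputs from multiple
    classifiers. Raw probabilities are mapped to a deviation (penalty) score
    and a support (reward) score through two non-linear transforms; classifier
    reliabilities define a Sugeno lambda fuzzy measure over classifier
    subsets; per-class deviation and support scores are aggregated across
    classifiers with the Choquet integral; the final label minimises the
    aggregated deviation, with agreement against the support pathway reported.
    Includes confusion-matrix metrics, a stratified k-fold cross-validation
    harness for imbalanced binary cohorts, a weighted-average ensemble
    baseline, a synthetic probability-score simulator, and a command-line
    interface over delimited score tables and JSON/YAML manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
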