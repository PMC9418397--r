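Package: thermograde
Title: Thermal Change Index Grading of Plantar Thermograms
Version: 0.1.0
Authors@R:
    person("Thermograde", "Maintainers", email = "maintainers@thermograde.dev",
           role = c("aut", "cre"))
Description: Tools for holistic severity grading of diabetic foot disease from
    plantar infrared thermograms. Segments the foot from ambient background,
    partitions it into the four plantar angiosomes (medial/lateral plantar and
    calcaneal artery territories), computes the Thermal Change Index (TCI) as
    the mean absolute deviation of regional mean temperatures from control-group
    references, and assigns a six-way severity label (control plus five diabetic
    grades). Includes a synthetic phantom generator emulating the control
    "butterfly" pattern and graded diabetic disruption, class-imbalance handling
    via inverse-frequency weights and offline/online augmentation, a compact
    rectangular-input convolutional neural network implemented in vectorized
    base R, stratified k-fold cross-validation with one-vs-rest class-wise
    metrics, and a command-line pipeline orchestrating the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
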