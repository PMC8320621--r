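Package: cdsurf
Title: Constrained Drop Surfactometry Analysis for the Lung Surfactant Bioassay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pathway for the constrained drop surfactometer lung
    surfactant bioassay: axisymmetric drop shape analysis (forward
    Young-Laplace integration and inverse surface-tension fitting),
    compression-expansion cycle segmentation and per-cycle minimum surface
    tension extraction, baseline quality control and inhibition calling,
    inhibitory-dose estimation, and two-scenario predictivity evaluation
    (sensitivity, specificity, predictive values, accuracy) of the in vitro
    inhibition call against GHS acute inhalation toxicity classification and
    rat clinical signs of respiratory toxicity. Includes a biophysical film
    simulator generating surface-tension/area traces with dose-dependent
    inhibition and margin-exact chemical outcome datasets, so the full
    pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
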