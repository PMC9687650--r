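Package: distecg
Title: Distant Transfer Learning for ECG Beat Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for electrocardiogram (ECG) beat classification with
    distant transfer learning. Provides Pan-Tompkins-style QRS detection and
    inter-R beat segmentation (band-pass filter chain, squaring, moving-window
    integration, adaptive dual thresholds), conditional generative adversarial
    networks with a logistic-mixture latent space for building auxiliary
    bridge domains, domain-feature-classifier negative-transfer-avoidance
    losses with a virtual-label joint/marginal discriminator, a three-stage
    multi-source transfer pipeline with ablation switches, a compact 1-D
    convolutional network backbone, stratified cross-validated evaluation
    (specificity, sensitivity, accuracy, percentage improvement), and
    synthetic generators for ECG traces with known fiducials and labeled
    vector domains with controllable shift and class imbalance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
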