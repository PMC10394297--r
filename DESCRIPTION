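Package: seizdg
Title: Patient-Independent EEG Seizure Detection via Feature Separation and
    Adversarial Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A domain-generalization framework for patient-independent
    epileptic seizure detection from multichannel EEG. Implements a
    multi-level temporal-spectral convolutional front-end built around a
    convolution-implemented Daubechies-4 discrete wavelet transform, a
    feature-separation network that disentangles category-related from
    patient-related components, and an adversarial invariant-feature network
    (global and per-class patient discriminators trained through a gradient
    reversal layer, plus a center loss) optimized with a joint minimax
    objective. Ships a synthetic multi-patient EEG cohort generator, a
    minimal EDF reader/writer, a leave-one-patient-out evaluation harness
    with ROC/AUC, an ablation suite, and t-SNE feature export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    nnet,
    stats,
    utils
Suggests:
    cluster,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
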