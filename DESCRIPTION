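Package: neosleep
Title: Sleep-State Classification for Preterm Infants from Cardiorespiratory
    Signals and Video-Based Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to classify neonatal sleep states (active sleep, quiet
    sleep, and the merged caretaking+wake state) from 30-second epochs of
    ECG-derived heartbeat series, respiratory effort, cardiorespiratory
    interaction and video-based motion counts. Provides a state-annotated
    multimodal recording simulator, a 91-feature extractor (34 cardiac, 41
    respiratory, 8 visibility-graph features of the cardiorespiratory
    interaction series, 8 actigraphy features), SMOTE class balancing with
    strict split-before-oversample discipline, and extremely-randomized-trees
    classification evaluated under leave-one-subject-out cross-validation
    with Cohen's kappa, ROC AUC and Gini feature importances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
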