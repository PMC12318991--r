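Package: fcselect
Title: Multi-Task Grey Wolf Feature Selection and Counterfactual
    Explanation for Functional Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class classification of functional brain networks from
    edge-level functional connectivity (FC) features.  Implements a hybrid
    filter weighting of edges (Fisher criterion, mutual information,
    dispersion), knee-point stratification of the ranked weight curve,
    probabilistic generation of related feature-selection tasks, a binary
    multi-task Grey Wolf Optimizer with cross-task knowledge transfer, a
    linear maximum-margin classifier with nested cross-validated
    evaluation (accuracy, sensitivity, specificity), and generation of
    diverse counterfactual examples (hinge validity loss, MAD-scaled
    proximity, determinant diversity) that move a patient's connectivity
    profile toward the classifier's control region.  Includes a synthetic
    connectome generator with planted discriminative edges so every stage
    can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
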