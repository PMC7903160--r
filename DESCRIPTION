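Package: unlearnr
Title: Adversarial Unlearning of Scanner Effects for Multi-Site Image Harmonisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an iterative adversarial "unlearning" framework for
    removing scanner/site and confound information from the learned feature
    representations of image-analysis networks, applied to brain-age regression
    and tissue segmentation. Training alternates a main-task step, a domain
    classifier step, and a confusion-loss step that drives the domain
    classifier's softmax outputs towards uniformity, so that the feature
    representation becomes uninformative of acquisition site while remaining
    discriminative for the task. Includes a synthetic multi-scanner phantom
    generator with configurable age-distribution overlap and confound-site
    correlation, NIfTI volume preprocessing, and a probe-based harmonisation
    metric (post-hoc scanner-classification accuracy versus chance) for
    quantifying residual site information in frozen features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
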