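Package: amcontrast
Title: Supervised Contrastive Learning with Angular Margins for Retinal Image Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a supervised contrastive learning objective in which the
    two stochastic augmentations of a source image (augmented positives) and other
    same-label images in the batch (same-label positives) receive different
    additive angular margins before the temperature-scaled softmax, together with
    the surrounding training framework for diabetic-retinopathy detection and
    grading from colour fundus photographs: stratified dataset splitting,
    stochastic double-view augmentation, a compact convolutional encoder with
    projection and classifier heads trained jointly on the combined cross-entropy
    plus angular-margin loss, alignment and uniformity diagnostics of the
    hypersphere embeddings, a classification metric suite (accuracy, precision,
    recall, F1, AUC), margin-grid and augmentation-pair ablation harnesses, and a
    synthetic fundus-like image generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
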