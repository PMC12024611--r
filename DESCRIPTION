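Package: acnegrader
Title: Semi-Supervised Feedback Pseudo-Label Learning for Ordinal Acne Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a feedback-based teacher-student pseudo-label
    framework for ordinal grading of facial acne images, together with the
    surrounding toolchain: an additive-margin softmax (AM-Softmax) loss over
    cosine logits, a lesion-safe RandAugment-style augmentation policy with a
    10x10 (N, M) search grid, a LinkNet-style encoder-decoder skin
    segmentation network for facial-skin region-of-interest extraction,
    clinical evaluation metrics (accuracy, precision, sensitivity,
    specificity, Youden index), a black-rectangle plus MD5-filename
    de-identification utility, and a synthetic fixture generator that renders
    graded face-like images with matching skin masks so every stage runs at
    desk scale with no external data. All networks run on a small built-in
    layer engine with explicit per-parameter gradients, which the
    teacher-student feedback chain requires.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
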