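Package: amodalr
Title: Self-Supervised Amodal Segmentation and Occlusion-Order Recovery for Occluded Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recovering the full (amodal) shape of partially occluded
    fruit from visible-region masks alone. Provides a synthetic occluded-scene
    generator with exact amodal ground truth built on mean-value-coordinate
    seamless cloning, a windowed-attention encoder-decoder segmentation network
    with an amodal-probability and boundary-uncertainty two-channel head, a
    self-supervised partial-completion training game with region-weighted and
    adversarial losses, pairwise occlusion-order graph inference from completion
    increments, and an evaluation suite (mIoU, invisible-region mIoU, pixel
    accuracy, pairwise ordering accuracies, mask average precision).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    pracma,
    stats,
    utils,
    grDevices
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
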