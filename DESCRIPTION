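Package: surgstereo
Title: Joint Stereo Disparity and Surgical Instrument Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A real-time-oriented multi-task stereo framework for
    endoscopic scenes that jointly predicts dense disparity maps and binary
    surgical-instrument segmentation masks from rectified stereo pairs. A
    shared convolutional encoder (lightweight or ResNet34) feeds a cascaded
    cost-volume disparity head and a U-Net style segmentation head. The
    package implements the full training stack on a compact CPU autodiff
    engine: supervised multi-scale disparity losses, weighted cross-entropy
    plus soft-dice segmentation losses, self-supervised photometric/SSIM/
    smoothness stereo losses, phased training schemes, evaluation metrics
    (EPE, Bad3, depth MAE, IoU), disparity ground-truth synthesis from 3-D
    point maps, and synthetic stereo scene generators that make every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
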