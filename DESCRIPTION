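Package: spikeformer
Title: Transformer-Based Wheat Spike Detection with Multi-Window Attention
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for detecting wheat spikes (ears) in RGB
    field images. Implements a hierarchical multi-window shifted-window
    attention backbone, an anchor-free one-stage detection head with
    IoU-family bounding-box regression losses (IoU, GIoU, CIoU and an
    aspect-ratio-weighted center-distance WIoU loss), COCO-convention
    average-precision evaluation, Pascal-VOC and COCO annotation input and
    output, and a seeded synthetic wheat-scene generator for testing and
    benchmarking. All tensor computation, including reverse-mode automatic
    differentiation for training, is implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
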