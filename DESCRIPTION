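Package: segreplay
Title: Diffusion-Driven Generative Replay for Class-Incremental Semantic
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Class-incremental semantic segmentation (CISS) under the
    binary-annotation regime of surgical anatomy datasets, where each image
    carries a pixel mask for exactly one "most prominent" structure and new
    classes arrive on disjoint images. Provides an unconditional denoising
    diffusion probabilistic model (DDPM) for generative replay, a compact
    fully-convolutional segmentation backbone with a dilated-convolution
    context block, dense feature distillation across intermediate layers and
    logits, an InfoNCE-style cross-model contrastive loss between real and
    generated images, confidence-thresholded pseudo-label merging, a multi-step
    incremental trainer, a synthetic surgical-scene generator for desk-scale
    benchmarking, and per-class Dice evaluation with grouped reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
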