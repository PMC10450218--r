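Package: caunet
Title: Channel Cross-Attention U-Net for Endoscopic Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of a U-style encoder-decoder
    segmentation network whose skip connections are a multi-scale channel
    cross-attention transformer, aimed at endoscopic images of nasal bleeding
    with spot and tendril vascular malformations. Provides a synthetic
    endoscopy-like image/mask generator, an image pipeline (min-max
    normalization, polygon-annotation rasterization, augmentation, dataset
    splitting), a confusion-count metric suite (IoU, precision, recall, F1,
    Dice) with focal loss, the network itself (squeeze-and-excitation gated
    grouped-convolution encoder, channel cross-attention skip transformer,
    channel+spatial attention decoder) on a compact reverse-mode autodiff
    engine with C++ kernels, and an Adam training loop with cosine-annealed
    learning rate and a freeze-thaw schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
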