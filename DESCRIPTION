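Package: yologinseng
Title: Single-Class Berry Detection with a Deep-Perception CSP Backbone Module and
    Channel-Pruning Compression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the YOLO-Ginseng detection method for ginseng berry umbels in
    canopy scenes: the C3f-RN deep-perception feature-extraction module (dual CSP-style
    branches with SimAM-tailed bottlenecks, a windowed-attention Swin stage, switchable
    atrous convolution and coordinate attention), its integration into a small-width
    single-class CSP detector with exact parameter and FLOP accounting, the BN-gamma
    network-slimming pipeline (L1-sparse training, global-quantile channel pruning,
    fine-tuning), precision/recall/AP at IoU 0.5 evaluation, and a deterministic
    synthetic berry-scene generator with YOLO-format dataset plumbing. All tensor
    operations run on a self-contained reverse-mode tape with compiled convolution
    kernels, so models can be built, trained and pruned at desk scale without external
    deep-learning runtimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    graphics,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
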