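Package: tsdnet
Title: Two-Leveled Video Stress Detection with Attention-Weighted Stream Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects psychological stress from short video clips by fusing a
    face-level representation (the feature difference between a clip's most
    expressive and most expressionless face, refined by multi-scale pooling
    attention and self-attention) with two action-level representations
    (frame-attention plus recurrent encoding of still frames and of dense
    optical flow). Streams are combined by a weighted integrator with local
    and global attention; early, loss-based early and late integration are
    provided for comparison. Includes a parametric synthetic stress-video
    generator with plantable face- and action-channel class signal, so the
    full pipeline can be trained and evaluated at desk scale on CPU, plus
    subject-level splitting, the training recipe, evaluation metrics, and
    ablation runners for the attention mechanisms, pooling combinations and
    integration strategies. All network layers are implemented natively with
    explicit backpropagation; convolution and pooling kernels use Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
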