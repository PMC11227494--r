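Package: echoclr
Title: Self-Supervised Contrastive Pretraining for Echocardiogram Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-efficient disease classification from echocardiogram videos via
    self-supervised pretraining. Implements multi-instance contrastive learning
    (NT-Xent over distinct same-study video pairs) combined with a frame-reordering
    pretext task, a 3D convolutional encoder (3D-ResNet18 and a reduced variant for
    desk-scale work), the full video curation pipeline (view-classification harness,
    threshold/convex-hull masking, downsampling), study-level data splitting and
    label titration, fine-tuning with early stopping and learning-rate grids,
    study-level AUROC/AUPR with percentile-bootstrap confidence intervals and a
    one-sided bootstrap test for AUROC differences, 3D Grad-CAM saliency with
    temporal max-projection, and a synthetic echo-like cohort generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
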