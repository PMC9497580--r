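Package: cxrtransfer
Title: Transfer-Learning Strategies and Saliency Agreement for Multi-Label
    Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for comparing transfer-learning
    strategies on multi-label radiograph-like images: quantile-clipping
    preprocessing, cross-dataset label mapping with max-probability
    aggregation, stacked generalization, tree classifiers on pooled
    convolutional image embeddings, and fine-tuning of a replaceable
    classification head. Predictions from several classifiers are combined
    by simple and entropy-weighted averaging and scored by per-label
    AUROC. A Grad-CAM implementation with model-level and population-level
    map averaging, quantile masking, bounding boxes and
    intersection-over-expert-area agreement supports localization checks.
    Ships a synthetic-data module (images with label-linked geometric
    signatures at known locations, prediction and embedding matrices with
    controlled signal, and small trainable fixture convolutional networks)
    so the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    ranger,
    png,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
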