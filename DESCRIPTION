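Package: simexplain
Title: Explainable Image Similarity with Siamese Networks and Grad-CAM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains Siamese verification models with a contrastive loss to
    score the similarity of image pairs, and explains each decision with
    factual and counterfactual Grad-CAM heatmaps computed at a chosen
    convolutional layer of the shared backbone. Includes weakly supervised
    crop refinement (binarized heatmap to bounding box) for cleaning training
    images, pair-verification metrics (accuracy, AUC, precision, recall),
    a synthetic shapes-on-noise dataset generator with ground-truth masks,
    and a command-line interface over the full pipeline. The convolutional
    forward and reverse passes are implemented in base R so that saliency
    gradients are exact and auditable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    jpeg,
    stats,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
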