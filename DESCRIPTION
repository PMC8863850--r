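Package: tileforest
Title: Lymph-Node Metastasis Risk Prediction from Tiled Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for predicting lymph-node metastasis of
    submucosal-invasive (T1) colorectal cancer from tiled histology images.
    Whole-slide rasters are tessellated into non-overlapping 299-pixel tiles
    and background is removed by a gray-scale pixel threshold; tile-level
    classifiers assign a cancer-class probability and a metastatic
    probability to each tile; per-case tile-probability profiles are
    summarised into an 18-parameter feature vector (tile counts, probability
    groups A-E, means, standard deviations, and a probability score summary)
    which is scored by an oversampled random-forest ensemble (500 candidate
    forests, top 20 by AUC, per-case maximum as the RF score) and stratified
    into very-low/low/moderate/high risk tiers. Includes a synthetic-data
    generator emulating labeled tissue textures and case cohorts of tile
    probabilities so the whole pipeline is trainable and testable without
    clinical whole-slide images, plus ROC/AUC, balanced-error cutoff,
    stratification tables, Fisher exact and Student t reporting, and
    whole-slide probability color maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    png,
    ranger,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
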