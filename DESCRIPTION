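Package: yieldformer
Title: Transformer-Based Early Soybean Yield Prediction from Canopy Image Time Series
Version: 0.1.0
Authors@R:
    person("Field Phenotyping Lab", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A wide-deep, attention-based pipeline for predicting plot-level
    soybean yield (kg/ha) from short time series of RGB canopy images plus
    categorical seed information (treatment x variety x seeding rate). Images
    are segmented into plant and soil streams with an excess-green index, each
    stream is encoded by a vision transformer, the per-timestamp stream
    features are fused by a Hadamard product and summarised by an encoder-only
    temporal transformer, and a shallow seed-embedding branch is concatenated
    before a shared regression head. Includes a synthetic plot-image generator
    with ground-truth masks and a configurable yield model, four baseline
    architectures (CNN-LR, CNN-LSTM, ViT-LSTM, ViT-T), training with Adam and
    early stopping, RMSE/R2/MAPE metrics, group-average and ridge-regression
    reference models, and a counterfactual seed-combination analysis. All
    neural components run on a small built-in reverse-mode autodiff engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
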