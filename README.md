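# yieldformer

Transformer-based early prediction of plot-level soybean yield (kg/ha) from
short RGB canopy-image time series plus categorical seed information
(treatment × variety × seeding rate).

## Who this is for

Field-phenotyping and agronomy groups that image small breeding/agronomy
plots a handful of times per season (here: three dates, June–August) and
want a yield estimate before harvest, together with a way to quantify how
much of the prediction comes from the images versus from the seed metadata.

## The model

Each plot record is a time series of `T` RGB images plus one of `n`
(default 51) seed combinations. The pipeline is a wide–deep architecture:

1. **Segmentation.** Every image is split into a *plant* image and a *soil*
   image (complementary maskings of the input) using an excess-green index
   `ExG = 2g − r − b` on chromaticity-normalised RGB, Otsu thresholding, 3×3
   morphological opening/closing and small-component removal.
2. **Dual ViT streams.** Two independent vision transformers (patch size 16,
   token width `D`, pre-norm blocks with multi-head attention
   `softmax(QKᵀ/√d_k)V` and GELU MLPs, learnable class token and positional
   embeddings) encode the plant and soil images to features
   `f_plant,t, f_soil,t ∈ ℝ^D` per timestamp.
3. **Fusion and temporal encoding.** Per timestamp the streams are fused by
   a Hadamard product `m_t = f_plant,t ⊙ f_soil,t`; an encoder-only temporal
   transformer (sinusoidal positional encoding, bidirectional multi-head
   attention blocks, mean pooling) maps the sequence `m_1..m_T` to one image
   representation `v`.
4. **Wide branch and head.** The seed combination is one-hot encoded and
   passed through three 16-unit dense layers to `f_seed ∈ ℝ¹⁶`; the head
   `Φ` applies dense layers (dropout 0.25) to `[v, f_seed]` and outputs the
   yield prediction `φ = Φ((f_plant · f_soil) + f_seed)`.

Training: MSE loss, Adam (lr 0.001), early stopping with patience 10 and
best-weight restore. Metrics: RMSE, `R² = 1 − RSS/TSS`, MAPE (%).

Baselines with the same fit/predict contract: `cnn_lr`, `cnn_lstm` (VGG-16
backbone), `vit_lstm`, `vit_t`, plus group-average reference predictors and
ridge-regression models on flattened channel-mean pixels.

Because the original 450-plot field dataset is private, the package includes
a first-class synthetic generator: perspective-foreshortened plant rows on
textured soil, logistic canopy-growth curves, ground-truth masks, and a
linear yield model with per-combination seed effects whose defaults
reproduce the published distribution shape (bulk 3500–5000 kg/ha,
left-skewed). Everything runs on a small built-in reverse-mode autodiff
engine (no deep-learning framework required).

## Worked example

```r
library(yieldformer)

ds   <- generate_dataset(24, tempdir(), scene = scene_params(image_size = 64),
                         rng_seed = 42)
y    <- ds$manifest$yield_kg_ha[ds$manifest$timestamp == 0]
d    <- describe_yield(y)
recs <- load_records(ds, image_size = 64)

seg   <- segment_plant_soil(recs[[1]]$images[[3]])
truth <- read_pgm(ds$manifest$mask_path[3], as_mask = TRUE)

combo <- vapply(recs, `[[`, 1L, "combo_index")
sp    <- split_dataset(combo, c(16, 4, 4), rng_seed = 1)
model <- build_model("proposed", preset = "small", rng_seed = 1)
model <- train_model(model, recs[sp$train], recs[sp$val],
                     train_config(max_epochs = 10, rng_seed = 1))
rep   <- metric_report(vapply(recs[sp$test], `[[`, 1, "yield"),
                       predict_yield(model, recs[sp$test]))
```

Output of the above:

```
n = 24 plots | mean yield 4586 kg/ha | skewness -0.34 | kurtosis 2.76
plant-mask IoU vs ground truth: 1.000
test RMSE 382.1 kg/ha | R2 -0.773 | MAPE 5.63%
```

The yield sample shows the generator's left skew; segmentation recovers the
ground-truth plant mask exactly on a clean scene. The negative test R² is
what a 10-epoch run on 16 training plots honestly produces — at the
acceptance scale (300 training plots, ~60–90 epochs) the same model reaches
test R² ≥ 0.5 and beats the group-average baselines (see
`tests/testthat/test-acceptance.R`, criterion 8).

A command-line surface wraps the stages:

```sh
Rscript inst/exec/yieldformer generate --out d/ --n-plots 20 --seed 7
Rscript inst/exec/yieldformer segment  --in d/manifest.csv --out seg/
Rscript inst/exec/yieldformer train    --manifest d/manifest.csv --out run/ --model proposed
Rscript inst/exec/yieldformer evaluate --checkpoint run/model.rds --manifest d/manifest.csv --out metrics.json
Rscript inst/exec/yieldformer analyze-seed --checkpoint run/model.rds --manifest d/manifest.csv --out cf.csv
```

## Counterfactual seed analysis

`counterfactual_seed_analysis(model, records)` predicts every plot under all
51 seed combinations (50 pseudo, one true), summarises each plot's
counterfactual distribution by its quartile box, and classifies the true
prediction as `inside_iqr`, `outside_iqr`, or `low_outlier`
(below `Q1 − 1.5·IQR`). `iqr_coverage()` aggregates the statuses — the
published analysis reports 47/68 = 69.1% of test plots inside the boxes, and
that all outliers fall *below* the boxes, i.e. seed information mainly helps
the model correct low-yield plots downwards.
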