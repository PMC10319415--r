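---
title: "Methods: wide-deep transformer yield prediction and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wide-deep transformer yield prediction and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(yieldformer)
```

## The prediction problem

A plot is a small experimental field unit carrying one seed combination
(treatment × variety × seeding rate) and one measured yield in kg/ha. The
inputs per plot are a short, date-ordered series of RGB canopy images
(three in the motivating study) and the categorical seed combination (51
levels). The task is regression to yield before harvest.

Two properties of such data shape the design. First, the two input sources
are heterogeneous: images are high-dimensional with spatial structure, the
seed combination is a single categorical variable — a *wide–deep*
architecture gives each source a branch of matching capacity and trains
both jointly (not an ensemble: gradients flow into both branches from one
loss). Second, plot images are taken at a diagonal, so near rows look wide
and far rows narrow; separating plant from soil pixels makes row geometry
and canopy fraction explicit to the model instead of asking the network to
disentangle them.

## Model

**Segmentation.** `segment_plant_soil()` computes the excess-green index on
chromaticity coordinates, `ExG = 2g − r − b` with `(r, g, b)` divided by the
per-pixel channel sum, thresholds it (Otsu on the ExG histogram by default,
with a plateau-midpoint tie-break; a fixed threshold is available), then
applies 3×3 morphological opening and closing and removes plant components
below `min_region = 16` pixels (speckle suppression that spares seedlings at
128×128). The plant and soil images are complementary maskings, so
`plant + soil` reconstructs the input bit-exactly and both streams keep the
fixed input shape. The underlying study states only the segmentation *goal*;
this training-free ExG/Otsu pipeline is our choice, replaceable behind the
`segmented_pair` contract. An all-constant image has no ExG histogram to
split; Otsu mode then warns and returns an all-soil mask.

**ViT streams.** Each stream is a standard pre-norm vision transformer:
patchify (row-major, `P = 16`), linear embedding to `D` dimensions, a
learnable class token and learnable positional embeddings, then `L` blocks
of multi-head attention (`d_k = floor(D/h)`, concatenated heads projected
back to `D`) and a GELU MLP, with layer norm before and residuals after each
sub-block. The image feature is the layer-normed class token. Published
shapes: `D = 128`, `L = 2`, `h = 3`, input 128×128×3. Where the source is
silent we follow transformer conventions and say so: GELU activation, MLP
hidden `4D`, learnable (not sinusoidal) patch positional embeddings, class
token included — the feature is indexed as token 0, which is only coherent
with an `(N+1)`-row positional embedding and a prepended class token. With
`h = 5` and `D = 128` the head width floors to 25 and the concatenation
(125) is projected to 128; flooring plus projection is the least surprising
reading of a non-divisible head count.

**Fusion, temporal encoding, head.** The two stream features are combined
per timestamp by an element-wise (Hadamard) product. The published fusion
formula composes a "dot product" of the two 128-d features with a 16-d seed
embedding; a scalar dot product cannot be concatenated meaningfully and the
experiment section states the embeddings are *concatenated*, so we read "·"
as Hadamard (keeping 128 dimensions) and "+" as concatenation. The fused
sequence passes through an encoder-only temporal transformer: dense input
layer, *sinusoidal* positional encoding
`PE[t, 2i] = sin(t/10000^{2i/D})`, `PE[t, 2i+1] = cos(·)`, three pre-norm
5-head blocks, then mean pooling over timestamps and a dense output layer to
128. Pooling is our choice where the source says only "an output layer":
it is length-agnostic and avoids privileging one timestamp of a 3-step
series. Attention here is bidirectional — early timestamps attend to late
ones — which the tests assert by perturbation. The seed branch one-hot
encodes the combination and applies three 16-unit ReLU layers; the head
applies three 128-unit ReLU layers (dropout 0.25 everywhere except the
linear output) to the concatenated 144-d vector.

**Baselines.** `cnn_lr` (VGG-16 features per timestamp, concatenated into a
256-unit L2-regularised dense regressor), `cnn_lstm` and `vit_lstm` (two
bidirectional LSTM layers; each direction carries 64 units so a layer emits
128), and `vit_t` (one ViT on the unsegmented image plus the temporal
transformer). All share the seed branch and head and the same fit/predict
contract. Two desk-scale concessions are documented rather than hidden: the
VGG dense widths default to 256/128/128 instead of 4096/4096 (a from-scratch
100M-parameter classifier head is useless at n ≈ 450), and a `small` preset
(64×64 input, `D = 32`, one block per stack, 4-conv-block backbone) exists
solely so that training-based tests finish in minutes on one CPU. The
`cnn_lr` L2 weight defaults to 1e-3; the source names the penalty but not
its weight.

## Training

MSE loss, Adam at learning rate 0.001, dropout 0.25, early stopping on
validation loss with patience 10 and restoration of the best-validation
weights — all as published. Batch size (16) and the epoch cap (200) are not
published and are configurable. Targets are internally z-scored on the
training split and predictions mapped back to kg/ha: with raw ~4500 kg/ha
targets the squared loss is ~10⁷ and Adam at 0.001 cannot move; the
standardisation is an implementation necessity, not a modelling change.
Splitting is an exact-size shuffle split, approximately stratified by seed
combination (round-robin over shuffled combination groups), so all 51
combinations reach the training set when sizes allow; whether the original
single 344/38/68 split was random or field-blocked is unknowable from the
text.

One training dynamic deserves a warning. Under this recipe the loss shows a
plateau of roughly 20–40 epochs before it drops: dropout noise initially
swamps the small systematic gradient, especially in the narrow wide-branch
layers. Early stopping at patience 10 survives the plateau only if the
validation loss is smooth enough for its slow drift to register — with a
validation set much below ~40 plots, most runs are stopped prematurely.
This mirrors the published setup's own 38-plot validation set; budget
validation plots accordingly rather than lowering the dropout rate.

All neural components run on a small reverse-mode autodiff tape
(`R/autodiff.R`): matrix-valued nodes, BLAS matmuls, a fused grouped
attention op (one batch of images is one graph), exact GELU via `pnorm`.
Gradients of every op are finite-difference-checked in the test suite.
Weight initialisation: fan-in uniform for dense/conv, truncated normal
(sd 0.02) for class/positional embeddings.

## The synthetic world

The field dataset behind the study is private, so the generator emulates
the statistical structure the method needs, and the tests state explicitly
what a green result establishes: that the *implementation* recovers signal
from a world with the assumed structure — not field-level accuracy.

A scene is `n_rows` horizontal plant bands over Gaussian-textured soil.
Far-end (top) bands shrink by `perspective_factor` (default 0.4), the
coverage cue the segmentation is meant to expose. Canopy coverage follows a
per-plot logistic curve `c(t) = c_max · plogis(rate · (t − midpoint))` with
`c_max ~ U(0.7, 1)`, `rate ~ U(1.2, 2.5)`, `midpoint ~ U(0.2, 1.2)` —
chosen once so that first-date coverage is sparse (≈5–25%) and last-date
coverage approaches closure, the qualitative June→August trajectory.
Colours default to soil (0.47, 0.35, 0.24) and foliage (0.24, 0.47, 0.20)
with per-pixel noise sd 0.04; the resulting ExG separation (~0 vs ~0.55) is
comfortably bimodal, which is what makes a ≥0.90 mask-IoU criterion a test
of the *pipeline* rather than of radiometric realism. Not modelled, hence
not established by any green test: lesions and weeds, specular soil,
shadows, camera pose variation, weather.

Yield is linear: `base + β_cov · c(T−1) + β_green · greenness +
effect(combo) + N(0, σ)` with defaults 3450, 1400, 300, σ = 110, and 20% of
combinations carrying effects drawn from U(−950, −650) (the rest
N(0, 60²)). The defaults were fixed against the published sample
statistics: they give ~96% of yields in 3500–5000 kg/ha, skewness ≈ −1.0
and kurtosis ≈ 3.2 (published: −1.26 and 3.09). The strongly negative
subset exists so the published qualitative finding — seed information
matters most for predicting *low*-yield plots — is testable as a property.
All randomness flows from one integer through per-plot/timestamp derived
seeds, so any single item regenerates identically in isolation.

## Numerical choices and degenerate inputs

- Otsu maxima can form a plateau (empty gap between modes); the threshold
  is the plateau midpoint.
- Quartiles in the counterfactual analysis use linear interpolation between
  order statistics (R's default type 7); the whisker rule is
  `Q1 − 1.5·IQR`. The source states the outlier rule but not the
  percentile convention.
- Kurtosis is reported in the Pearson (non-excess) convention,
  `m₄/m₂²` — the published 3.09 for a near-normal sample identifies it.
- MAPE is returned in percent; the published formula omits the ×100 but
  every table prints percent.
- `R²` uses the evaluation set's own mean in TSS, which is what allows the
  published negative value for the weakest reference model.
- T = 1 sequences, all-plant and all-soil images, constant targets
  (`sd = 0` guards), and missing timestamp images (error naming the plot)
  are all exercised in the tests.
- The counterfactual analysis computes the image branch once per plot and
  re-runs only the head per combination, which both saves 50 forward passes
  and makes the true-combination counterfactual *bit-identical* to the
  ordinary forward pass by construction.

## External formats

Images are written as binary PPM (P6) and masks as PGM (P5) rather than
PNG: the deployment environment guarantees no PNG codec for R, and NetPBM
is self-describing, lossless for 8-bit data and universally readable.
Configs round-trip as JSON for the same reason (no YAML parser guaranteed).
Ridge reference models are fitted with glmnet (`alpha = 0`).

## Known limitations

- The renderer's perspective is height-only foreshortening; no lens or
  pose model.
- The `published` preset trains from scratch; no pretrained backbones are
  available offline, so published-scale accuracy claims are out of reach by
  construction.
- Training the VGG-sized baselines end-to-end at 128×128 is possible but
  slow in pure R; the baselines are validated structurally and at smoke
  scale.
- The counterfactual analysis quantifies the model's *reliance* on seed
  information; it supports no causal claims about treatments.
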