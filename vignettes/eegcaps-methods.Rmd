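---
title: "Methods: EEG seizure classification with capsule and transformer heads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG seizure classification with capsule and transformer heads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data model

Single-channel EEG segment classification, in two tasks: a binary task
(seizure vs non-seizure) and a five-class task distinguishing ictal
recordings (class a), interictal recordings from the tumour region (b) and
the healthy region (c) of surgical patients, and surface recordings with
eyes closed (d) and open (e). The canonical data layout is one row per
1-second segment of 178 samples (178 Hz); raw recordings of 4097 samples
(~23 s) are restructured into 23 consecutive non-overlapping 178-sample
chunks each, discarding the trailing 3 samples (`segment_recordings()`),
which is the only reading under which 23 chunks of 178 samples tile a
4097-sample recording. A balanced five-class corpus therefore maps to a
1:4 imbalanced binary corpus (class a against everything else), which is
what motivates the oversampling module.

## The classifier family

All five variants share a 1-D convolutional backbone and differ in the
classification head:

* **Backbone.** Six blocks of same-padded, kernel-3 convolutions with
  batch normalisation and SELU, with channel plan
  2×32, 2×64, 3×128, 3×256, 3×512, 3×512; each block ends with max pooling
  (size 2, stride 2, floor) and dropout 0.5. A 178-sample input yields a
  (2, 512) feature map. Where a description of this network gives
  conflicting depictions of the deepest stage (six 512-channel layers in
  prose, nine in a figure caption) we follow the prose; likewise the dense
  stack below keeps the duplicated 128 of the prose. A pool that would
  shrink the time axis below one position is skipped (with a message);
  this is what makes 40-sample PCA inputs viable and reproduces the
  (1, 512) map they are documented to produce. The skip rule is our
  reading; uniform floor pooling alone cannot produce those shapes.
* **Dense head** (`cnn_fully`): global max pool over time, then dense
  layers of 1024, 512, 256, 128, 128, 64, 32, 16 units (each with batch
  normalisation and SELU), then a softmax output layer.
* **Capsule head** (`cnn_caps`): the feature map is cut into primary
  capsules of width `num_caps = 16`, squashed, linearly transformed into
  per-class prediction vectors, and routed for `r = 3` iterations of
  routing-by-agreement; class scores are a softmax over the output-capsule
  lengths. We read the single stated capsule hyperparameter
  (`num_caps = 16`) as the capsule *width* (both primary and output), and
  expose the counts in configuration since the alternative reading
  (16 primary capsules) cannot be ruled out. The routing softmax
  normalises over the *output* index, matching the written procedure
  (`c_ij = exp(b_ij)/Σ_k exp(b_ik)`). `r = 3` follows the convention of
  the original capsule formulation; the value is not stated in the source
  description.
* **Transformer heads** (`cnn_tf`, `cnn_tf_fully`, `cnn_tf_caps`):
  post-norm encoder blocks, `X → LN(X + MHA(X)) → LN(· + MLP(·))`, with
  multi-head scaled dot-product attention and a SELU MLP of hidden width
  4 × d_model (the ratio is unstated in the source; 4 is the field
  standard and it is configuration-exposed). Head/block defaults per
  variant: `cnn_tf` 16 heads × 2 blocks, `cnn_tf_fully` 16 × 1,
  `cnn_tf_caps` 8 × 1. `cnn_tf` classifies from the time-mean of the
  encoder output (the usual global-average idiom; the pooling is unstated
  in the source). No positional encoding by default — the encoder sees at
  most two positions — but sinusoidal encoding is available behind a flag.

Training is Adam (learning rate 0.001), batch 128, 500 epochs by default,
minimising softmax cross-entropy. For capsule heads the cross-entropy is
taken over softmaxed capsule lengths; the classical margin loss is
available behind `use_margin_loss` but measurably underperforms
cross-entropy at the scaled-down sizes this package tests, so it is not
the default.

## The network engine

No deep-learning framework is used: every primitive (convolution via
im2col, batch normalisation, SELU, max/mean/global pooling, inverted
dropout, dense, layer normalisation, multi-head attention, the capsule
layer with dynamic routing, Adam) is implemented in plain R with
hand-derived backward passes, and each backward pass is verified against
central finite differences in the test suite. Two deliberate numerical
choices:

* **Routing gradients.** The forward pass is the exact routing loop. The
  backward pass treats the coupling coefficients `c_ij` as constants,
  letting gradients flow through `s_j = Σ_i c_ij û_j|i` only — a common
  simplification in published capsule implementations that avoids
  unrolling the routing recurrence. At `r = 1` the couplings genuinely are
  constants, which is what the finite-difference test exercises.
* **Batch-norm re-estimation.** Dropout feeds every normalisation layer
  here (each conv block ends with dropout), so running moments collected
  during training see inverted-dropout-scaled activations. At inference
  dropout is off and the activation variance is systematically smaller —
  the known "variance shift" pathology — and at the small widths used for
  desk-scale experiments the mismatch compounds across the ~24
  normalisation layers badly enough to destroy inference accuracy while
  train-mode accuracy is fine. `train_model()` therefore ends with one
  calibration pass: weights frozen, dropout off, the training data (capped
  at 1024 evenly spaced rows) streamed through the network layer by
  layer, and every batch-norm layer's running moments replaced by the
  moments of its true inference-time input. This is the standard
  re-estimation remedy and it is always on.

Other numerics: LeCun-normal weight initialisation (appropriate for SELU);
batch-norm ε = 1e-3, momentum 0.9 during training; ε = 1e-7 in squash and
layer-norm denominators; max-pool ties break toward the earlier position;
Adam ε = 1e-7. All randomness flows through named RNG streams derived from
a single seed by stage-name hashing, so stages are independently
reproducible and bit-identical under a fixed seed.

## Preprocessing conditions

Four dataset conditions: `any` (identity), `scaling` (per-feature
standardisation with population 1/n variance, ε = 1e-12), `pca`
(projection to 40 components — the stated outcome, fixed rather than
chosen by a variance criterion, matching the (None, 40, 1) input shapes
the reduced models expect), and `scaling_pca` (both). All parameters are
fit on the training partition only and applied unchanged elsewhere;
whether the original experiments fitted on the full data is unstated, so
their figures may reflect a more optimistic (leaky) protocol. PCA
component signs are fixed deterministically (largest-magnitude loading
positive) for reproducibility.

## Class balancing

`smote()` and `adasyn()` are implemented from scratch for the binary task
(the imbalance is 1:4 there; the five-class corpus is balanced by
construction). SMOTE interpolates uniformly between a minority point and
one of its k = 5 nearest minority neighbours (k is the canonical default;
unstated in the source). ADASYN computes, for each minority point, the
fraction of majority points among its k nearest neighbours over the full
dataset and allocates the required synthetics proportionally (uniform
fallback when the minority is entirely interior); rounding residue goes to
the highest-ratio seeds one by one. Balancing is applied to the training
partition only, to keep held-out folds synthetic-free; whether the
original protocol balanced before or within cross-validation is unstated.

## Evaluation

`confusion()` uses predicted-rows × actual-columns orientation (the
transpose of the common convention, kept for consistency with the tables
this package mirrors; the serialised form labels both axes). `metrics()`
computes accuracy and one-vs-rest per-class precision/recall/F1/support
with macro averages; division-by-zero cells report 0 with a flag.
`cross_validate()` is stratified k-fold (k = 10 by convention) with
per-class fold counts within one sample of proportionality.
`gradcam_1d()` computes 1-D Grad-CAM: class-score gradients w.r.t. a
chosen convolutional feature map, time-averaged into channel weights, a
ReLU-rectified weighted sum, linear interpolation to the input length, and
per-map normalisation to [0, 1].

## The synthetic generator

`synth_generate()` emulates the class-conditional structure the
classifiers rely on, in microvolt-like units at 178 Hz: class a is a 3 Hz
spike-and-wave discharge at ~10× background amplitude (150 µV wave, sharp
~25 ms spikes at 1.5× the wave, heavy-tailed Student-t noise); classes b
and c are AR(2) background (coefficients 1.0, −0.5; innovation sd 10,
giving ~15 µV background) with sporadic biphasic spikes at 1.5/s vs
0.5/s — deliberately confusable, differing only in spike rate; class d
carries a strong 10 Hz alpha rhythm (60 µV); class e an attenuated alpha
(8 µV) plus broadband noise (20 µV). Defaults were chosen once, as
physiologically plausible orders of magnitude that make the binary task
easy and leave b/c overlapping (mirroring the real data's reported
hardest pair). The amplitudes and the spike width were set at design time
from a spectral calculation — narrow spikes at 3 Hz would have pushed
enough harmonic power into the 8–12 Hz band to rival class d's alpha, so
the spikes are 25 ms wide and the alpha amplitude 60 µV, keeping the
alpha band dominated by class d as intended.

What the generator does *not* emulate: multi-channel spatial structure,
artifacts (blinks, EMG), non-stationarity across recording sessions,
patient-level variability, or the true waveform diversity of ictal
patterns. Passing tests on this data demonstrate that the pipeline and
the optimisation behave correctly and that the architectures can exploit
amplitude/spectral class structure — not that the reported real-data
accuracies are reproduced. Real-data headline figures additionally
require the external corpus and full-scale (500-epoch, GPU) training,
both outside this package's test envelope.

## Desk-scale study sizes

The test suite and worked examples run every architecture at
`width_scale = 8` (conv channels and dense widths divided by 8), 30
epochs, batch 32, on 100 synthetic segments per class with a stratified
80/20 split; the sanity thresholds at that size are ≥ 90% binary test
accuracy and ≥ 60% five-class (chance 20%, with b/c designed to overlap).
Gradient and routing oracles run on deliberately tiny instances
(n ≤ 4 capsules, d ≤ 4) where naive loop implementations are exact
references. These sizes are the package's chosen reproducible study
configuration; the full-scale configuration (width_scale 1, 500 epochs,
batch 128) is the default in `architecture_spec()`.

## Known limitations

* Training is single-threaded plain R: practical for the scaled study
  sizes, not for 500-epoch full-width runs.
* Routing backward uses detached couplings (above); gradients are exact
  only at r = 1.
* The classical-ML harness delegates to rpart/nnet/ranger/e1071/
  randomForest/xgboost. Two backends are intentionally minimal in-package
  implementations (Minkowski-p brute-force kNN; hinge-loss SGD linear
  classifier with l1/l2/elasticnet penalties) because no installed package
  exposes those exact estimators; nnet fits a single logistic hidden
  layer, so multi-layer MLP widths beyond the first and the `relu`
  activation label are recorded with the fit rather than changing the
  optimiser.
* Five-class accuracy at desk scale is bounded well below 100% by design
  (b/c overlap); it measures optimisation health, not attainable ceiling.
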