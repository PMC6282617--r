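---
title: "Counting rosette leaves by multi-modal deep regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting rosette leaves by multi-modal deep regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Leaf count is a standard developmental trait for rosette-shaped plants
(Arabidopsis, tobacco seedlings, komatsuna): it tracks growth stage,
flowering time and stress response. Counting by eye does not scale to
modern imaging rigs, and segmentation-based counters tend to break when
leaf overlap, species or camera change. `leafcounter` implements the
alternative: treat counting as a direct image-to-number *regression*
learned from images annotated only with a total leaf count, with no
per-leaf delineation.

Phenotyping rigs increasingly record several imaging *modalities* of the
same plant — visible light (RGB), near-infrared reflectance (NIR) and
chlorophyll fluorescence (FMP) — with different sensors, resolutions and
alignments. Each modality fails differently (RGB suffers background
clutter and color confusion; fluorescence is photon-starved and noisy;
NIR is often the cleanest), so the package's network is built to consume
any subset of them and let training decide what to keep from each.

## The model

The network has three parts, all trained jointly:

1. **Modality branches.** Each modality is processed by its own
   residual-convolutional branch with *unshared* weights. A branch ends
   in global average pooling followed by a fully connected layer of
   `branch_feature_dim` (default 1024) ReLU units. Global average
   pooling is what makes the feature length independent of the input
   image size; the admissible minimum size depends on the backbone. Two
   backbones are provided: `resnet50`, the full 50-layer bottleneck
   architecture (minimum input 200×200), and `tiny_resnet`, a three-stage
   residual network (stem stride 2, stages of 32/64/64 channels, minimum
   input 32×32) sized so that the full protocol runs on a desktop CPU in
   minutes. In this build the 50-layer backbone is randomly initialized;
   its batch-normalization layers are realized as trainable per-channel
   scale/shift with the running statistics absorbed, the standard
   frozen-statistics regime used when fine-tuning on small data.
2. **Element-wise maximum fusion.** Branch feature vectors are combined
   index-wise by `max`. The operation is parameter-free, idempotent,
   commutative and monotone, and is defined for any nonempty subset of
   branches — which is why the model can be extended or restricted to
   new modality sets without architectural change. During training the
   gradient of each fused coordinate flows to the (first) branch that
   attains the maximum.
3. **Non-linear regression head.** The fused descriptor feeds a fully
   connected layer of `regressor_hidden_dim` (default 512) ReLU units
   and then a single linear output neuron producing a real-valued count.
   Predictions are rounded only at test time; ties round half away from
   zero and negative raw outputs clamp to zero (the network is free to
   regress below zero early in training, but a count is nonnegative).

## Training protocol

The loss is the mean squared error between the raw prediction and the
integer ground truth, plus an L2 penalty `λ‖W‖²` on the regressor hidden
layer's weight matrix with `λ = 0.02`. Optimization uses
adaptive-moment gradient descent (Adam, β₁ = 0.9, β₂ = 0.999); the
default learning rate is `η = 0.0001`, appropriate when starting from a
pre-trained backbone. Training images (only) are augmented with random
rotations (uniform on [0°, 360°) — top-view rosettes have no preferred
orientation), isotropic zoom in [0.9, 1.1] and per-axis shifts up to
±10% of the side, with the *same* geometric transform applied to every
modality of a sample. Early stopping monitors validation MSE: training
halts after 10 consecutive epochs without improvement and the
best-epoch weights are restored. Batch size defaults to 16.

Where this package trains its `tiny_resnet` backbone from random
initialization, it uses a learning rate of 10⁻³; the 10⁻⁴ default is
tuned to nudging an already-functional pre-trained feature extractor,
and from-scratch training of the small backbone converges an order of
magnitude faster at the larger step size.

Cross-validation re-randomizes the full split at every fold (rather
than rotating disjoint folds), matching the re-splitting protocol used
for small counting datasets: with only ~128 images, fold-to-fold
variance dominates and independent re-splits estimate it directly.
Fine-tuning starts from a copy of a trained network and continues
training with a stated number of new-domain images; the progressive
protocol (`n_train_images = c(7, 14, 21, 27)` and similar) fine-tunes an
independent copy per size, always from the same pre-trained weights.

## Preprocessing

Images are histogram-equalized per channel (to absorb illumination
differences between rigs) and resized to 320×320. When heterogeneous
sensors are combined, a modality whose native side is below the
backbone minimum of 200 pixels is instead upsampled to 240×240 and the
remaining modalities are left on the standard rule. Equalization is
applied *before* resizing so that the intensity mapping is computed
from native-resolution statistics rather than from interpolated pixels.
Resizing is bilinear in both directions. Constant (flat-histogram)
images pass through equalization unchanged. Inputs with values above 1
are assumed 8-bit and divided by 255.

## Evaluation metrics

With per-image errors `d_i = predicted_i − truth_i`, the package
reports the community-consensus set: DiC (mean and SD of `d_i`), |DiC|
(mean and SD of `|d_i|`), MSE, percentage agreement (`d_i = 0`), the
±1-leaf fraction, and R². Two conventions deserve a note:

* **Population SD.** Standard deviations divide by `n`, under which
  `MSE = mean(d)² + sd(d)²` holds *exactly*. Published summary tables
  of these metrics are consistent with this identity (e.g. a reported
  DiC of 0.19 (1.24) alongside an MSE of 1.56 ≈ 0.19² + 1.24²), so the
  package adopts it and its tests assert the identity to 10⁻⁹.
* **R² as coefficient of determination.** R² is computed as
  `1 − SS_res/SS_tot` of predicted versus truth, not as a squared
  correlation. The distinction matters: a systematic +1 bias leaves the
  correlation at 1 but is penalized by the determination coefficient,
  and only the latter satisfies "R² = 1 exactly when predictions equal
  the truth" and "R² = 0 for a constant prediction at the truth mean".

Method comparisons over a shared test set use a two-sided paired t-test
on per-image absolute-error differences; the degenerate zero-variance
case returns `p = 1` with a warning instead of failing.

## The synthetic rosette generator

No real plant dataset ships with the package. Instead, `generate_plant`
and friends render annotated rosettes whose ground truth is exact by
construction, so every stage of the pipeline — loading, preprocessing,
training, evaluation, saliency — is exercisable end to end.

A plant is a set of ellipse blades (plus a short petiole segment)
placed around a jittered center at successive divergence-angle offsets
of 137.5°, the golden angle of rosette phyllotaxis; blade size grows
with leaf age rank, so older leaves are larger. An `occlusion_factor`
in [0, 1] pulls blades toward the center: at 0 the blades are pairwise
disjoint (the mask has exactly one connected component per leaf, which
the tests verify by connected-component labeling), at 1 they pile onto
the center as in mature rosettes. Each modality renders the same
geometry at its own raster size with its own contrast model: RGB draws
green blades over a textured soil (or tray/dark) background with
optional greenish *clutter* blobs that can be mistaken for blades; NIR
renders a bright plant on a dark background (the cleanest separation);
FMP renders a bright plant on a near-black background. Per-modality
additive Gaussian noise defaults to SD 0.02 (rgb), 0.01 (nir) and 0.05
(fmp). Default raster sizes deliberately differ per modality (64², 80²,
48²) because multi-sensor rigs are label-aligned but not pixel-aligned.

Defaults were chosen once as a plausible desk-scale emulation: counts
up to ~20, blade lengths 8–24 px on a 64-px canvas, width 4–11 px,
center jitter 3 px, occlusion 0.2, size jitter ±10%. Time series use a
saturating growth curve per leaf with persistent positions and
non-decreasing counts. All randomness flows from one integer seed with
a per-sample substream (`seed + i`), so datasets are prefix-stable when
their size changes.

What the generator does *not* emulate: photorealistic texture, leaf
venation and serration, specular highlights, moss and soil biota,
diurnal leaf movement, camera distortion. Passing the package's tests
therefore demonstrates that the architecture, optimization and
protocols work as specified — not that any particular accuracy carries
over to real imagery, where a full-scale backbone and pre-trained
weights are the appropriate configuration.

## Study configurations used by the tests

The test suite trains real models; sizes were fixed once so the whole
suite runs on one CPU core in well under half an hour:

* **Count recovery** — the reference study: 64×64 RGB rosettes, counts
  1–12, 300 train / 100 validation / 100 test, `tiny_resnet` with the
  default 1024/512 widths, η = 10⁻³, up to 20 epochs, patience 10,
  seed 0. The acceptance check asks for at least 70% of test images
  within ±1 leaf and mean |DiC| ≤ 1 — a deliberately scaled-down
  analogue of the ~80% ±1-leaf performance reported for full-scale
  counters on real benchmarks.
* **Multi-modal gain** — 48×48 with induced single-modality ambiguity
  (rgb clutter 0.5, nir clean, fmp noise SD 0.15), 120/40/40, 12
  epochs, seeds 1–3: the fused three-branch model's mean test MSE must
  not exceed the best single-modality model's.
* **Fine-tuning and agglomeration trends** — style A (soil background,
  clutter 0.4) versus style B (tray background, no clutter, slimmer
  blades). Fine-tuning a style-A model with 10/20/40 style-B images
  must give non-increasing mean test MSE over seeds 1–3. A companion
  check trains on a pooled 20 + 20 A/B set versus 40 A-only images and
  compares test MSE on A: it probes whether heterogeneous pooling can
  substitute for in-domain data at a *fixed* training budget. Note
  that this is a stricter question than growing a training set by
  pooling additional datasets: with style A's errors dominated by
  clutter/blade confusion that style B never exhibits, trading
  in-domain images away can cost more than the added diversity returns
  (see Limitations).
* **Saliency localization** — occlusion maps (8-px patches, stride 8)
  on trained models from three seeds: the mean absolute count change of
  plant-mask patches must exceed that of pure-background patches.

## Saliency: what does the network count?

`occlusion_count_map` slides a square patch over one modality (leaving
the others untouched), replaces it with a fill value (per-channel image
mean, or mid-gray) and records the change in the raw predicted count.
Occlusion sensitivity was chosen because it is model-agnostic and
directly interpretable in count units; gradient-based attribution
variants are out of scope. `branch_activation_map` complements it with
the channel-mean activation of a branch's first residual block, a
coarse picture of where each modality branch responds.

## Numerical choices and edge cases

* Weight initialization is He-scaled Gaussian, seeded; building the
  same configuration twice with the same seed gives identical
  parameters, and a fixed training seed makes whole runs reproducible
  (single-threaded).
* Max-fusion gradients route to the first branch attaining the
  maximum; exact ties are measure-zero under continuous weights but the
  tie-break is fixed for determinism.
* The early-stopping rule is "no strict improvement of validation MSE
  for `patience` consecutive epochs"; the first epoch always counts as
  an improvement (over an infinite incumbent), so a monotonically
  worsening trajectory stops at epoch `patience + 1` with best epoch 1.
* `finetune(n_train_images = 0)` performs no optimizer step and returns
  weights identical to the pre-trained input.
* Checkpoints are single-file archives (format version, configuration,
  weights); loading rebuilds the graph and restores weights exactly.
* PNG round-trips quantize intensities to 8 bits; ids and counts
  round-trip exactly.

## Known limitations

* No GPU path: the engine is BLAS-backed CPU code. Training the full
  50-layer backbone at 320×320 is functional but not practical here;
  it exists for architectural fidelity, input-contract enforcement and
  inference-shape checks.
* No pre-trained weights are bundled, so `use_pretrained_backbone`
  raises an informative error rather than silently training a random
  "pre-trained" network.
* The generator's simplicity means accuracy numbers on synthetic data
  should be read as protocol validation, not as phenotyping accuracy
  claims.
* Data agglomeration helps by *growing* the training pool; at a fixed
  total budget, replacing in-domain images with off-style ones is not
  guaranteed to help and, in the bundled synthetic setting, measurably
  hurts when the held-out style's hardest confounder (background
  clutter) is absent from the other style. The test suite runs this
  comparison and reports it as the failing case it is.
* Cross-modality pixel registration is deliberately absent (the fusion
  happens at the feature level, after global pooling), and depth-like
  modalities are not modeled.
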