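---
title: "Methods: multi-task attention U-Net for breast ultrasound"
author: "nunet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task attention U-Net for breast ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nunet)
```

## The problem

Breast ultrasound images are low-contrast, speckle-textured, and carry
lesions whose pixel areas span roughly two orders of magnitude. Two
clinically coupled tasks are solved jointly on the same image: deciding
whether a lesion is present at all (binary lesion-presence classification,
with benign and malignant merged into the positive class), and delineating
the lesion (binary segmentation). This package implements the N-Unet
multi-task architecture for that setting, together with the full
experimental protocol around it: a synthetic phantom generator, a
leakage-free stratified five-fold split, training, classification-gated
inference, a metric suite, and a complexity audit.

## Architecture

The network is a U-shaped encoder-decoder with two extra streams of
computation:

* **Encoder with adaptive feature fusion (AFF).** The main path is the
  classic chain of Double Conv (two 3x3 conv + batch norm + ReLU) blocks
  with 2x2 max-pooling, with channels 16-32-64-128-256 on a 256x256 input.
  Alongside it runs an AFF chain: at each level, the previous AFF output is
  pooled into alignment and passed through a depthwise-separable
  convolution (3x3 depthwise + 1x1 pointwise), squeeze-and-excitation (SE)
  recalibration (reduction 16) and dropout 0.2, then concatenated with the
  main-path feature and fused by two conv+BN+ReLU stages with a second SE
  in between. The first AFF takes the stem features as both inputs. The
  final AFF output feeds the 512-channel bottleneck (a single 3x3
  conv+BN+ReLU at 8x8), and the per-level AFF outputs are the skip
  features.
* **Decoder with cross-level attention enhancement (CLAE).** Each decoder
  level upsamples bilinearly (2x), halves channels with a 3x3 convolution,
  and refines the skip feature with CBAM (channel attention from
  average- and max-pooled descriptors through one shared C -> C/16 -> C
  MLP, then spatial attention through a 7x7 convolution on channel-pooled
  planes) followed by an additive attention gate
  (alpha = sigmoid(Wa ReLU(W1 Xs + W2 Xu)) with 1x1 projections). The gated
  skip is concatenated with the upsampled feature and fused by a Double
  Conv.
* **Heads.** Segmentation: a 1x1 convolution to one channel plus sigmoid,
  at full resolution. Classification: global average pooling of the
  bottleneck followed by a 512 -> 1024 -> 2 fully connected head; logit
  index 1 is the lesion class.

### Calibration of under-specified widths

The published description pins the channel schedule ("256x16x16" and
"512x8x8" on a 256x256 input), the attention hyperparameters (reduction 16,
7x7 spatial kernel, dropout 0.2) and the complexity budget (8.95 M
parameters, 14.74 G), but leaves several widths open: the stem depth, the
bottleneck depth, the upsampling operator, the AFF side-branch widths and
the attention-gate widths F. We resolved them by treating the complexity
audit as the fidelity check, adjusting only those free knobs until both
printed figures are met at two-decimal rounding:

* stem: Double Conv (3 -> 16); bottleneck: a single 3x3 conv block
  (256 -> 512);
* upsampling: bilinear 2x followed by a 3x3 conv halving channels
  (transposed convolutions would overshoot the parameter budget);
* AFF side-branch pointwise widths (25, 32, 64, 128, 96) per level;
* attention-gate widths F = (16, 16, 32, 64, 128), i.e. F = C at the top
  level and C/2 below.

With these defaults `countParams()` reports 8,952,544 parameters (8.95 M)
and `countMacs()` reports 7.372 GMACs, printed as 14.74 G under the
FLOPs = 2 x MACs convention (one multiply and one add per accumulate) that
profiler outputs are conventionally reported under; both match the printed
budget at two-decimal rounding. The audit also reports per-block
breakdowns, and totals always reconcile bit-exactly with them.

```{r}
model <- buildNUnet(modelConfig())
complexityReport(model)
```

## Losses

* **Focal-BCE (classification).** Per sample,
  `-omega_i (1 - p_t)^gamma log(p_t)` with `p_t` the predicted probability
  of the true class, `gamma = 2`, and `omega_i = N_neg / N_pos` for lesion
  samples (1 for normals), recomputed on each training fold. Probabilities
  are clamped at 1e-7 so the logarithm stays finite. The two-logit softmax
  reduces to a sigmoid of the logit difference, which is how the graph
  implementation computes it.
* **Dice (segmentation).** `1 - (2 sum(pg) + eps) / (sum p + sum g + eps)`
  per image, `eps = 1e-5`, averaged over the batch. Normal images
  participate with an all-zero ground truth, supervising the branch toward
  empty output on normals; evaluation excludes them instead (see below).
* **Adaptive multi-task combination (AMTL).** `L = (1/D) sum_i [ L_i /
  (2 sigma_i^2) + log sigma_i ]` with `D = 2` tasks. The uncertainties are
  learned through `s_i = log sigma_i^2` (positivity is automatic), both
  initialized at `s_i = 0`, i.e. `sigma_i = 1`, where the loss is exactly
  `(L_cls + L_seg) / 4`. Holding `L_i` fixed the stationary point is
  `sigma_i = sqrt(L_i)`. All losses are batch means rather than sums, so
  the loss scale does not depend on batch size.

## Classification-gated inference (CSB)

At inference the discrete classification decision sigma (0 =
nodule-containing, 1 = normal; argmax with ties resolved toward the lesion
class) scalar-gates the segmentation map: `S_hat = (1 - sigma) S`. The gate
adds no parameters, information flows strictly one way, and because the
gate is binary it commutes with the 0.5 binarization threshold. Its risk is
asymmetric by construction: a false-negative classification
deterministically erases a true lesion, while a false positive merely
leaves the raw map untouched. The gate is inference-only; training always
sees the raw segmentation output.

## Data protocol

Lesion area A is the foreground pixel count of the mask at the
standardized resolution. Lesion-positive samples are tiered small / medium
/ large by the empirical 33% and 66% quantiles of A (linear interpolation
between order statistics at index 1 + (n-1)p, the most common convention);
zero-area normals are excluded from the quantiles and from the tiers.
Tier boundaries are left-closed: A = alpha is medium, A = beta is large.
Splitting stratifies by category x size tier: each stratum is shuffled once
and cut into five near-equal blocks; fold f tests on block f, validates on
block f+1 (mod 5), and trains on the remaining three — the only rotation
consistent with five folds and an approximate 6:2:2 ratio.

Splitting strictly precedes augmentation. Training samples are augmented
with random bicubic resizing (scale 0.8-1.25), right-angle rotations
(90/180/270 degrees, probability 0.75), small rotations in [-10, 10]
degrees, center cropping to 0.9, and horizontal/vertical flips (p = 0.5
each); masks always use nearest-neighbor interpolation and stay strictly
{0,1}-valued. The published recipe names these operations but not their
probabilities; the values above are conventional defaults and are exposed
in the policy object. Evaluation uses deterministic preprocessing only:
resize plus per-image min-max normalization. The augmenter refuses any
sample not flagged as training, which makes leakage of validation or test
derivatives into the training stream structurally impossible, and tests
assert it.

## Evaluation

Classification reports accuracy, precision, recall and F1 with lesion as
the positive class, plus trapezoidal ROC-AUC computed on the pre-gate
lesion probability (the continuous score, not the binary decision).
Segmentation metrics (IOU, Dice, pixel accuracy, sensitivity, precision)
are computed per image on pixel counts and averaged; images with empty
ground-truth masks are excluded because their overlap ratios are undefined
or convention-dependent. A ratio with a zero denominator (e.g. pixel
precision under an empty prediction on a lesion image) is reported as
absent (NA), never as 0 or 1 — absence is the honest encoding. Fold
aggregation reports the sample mean and SD (k-1 denominator) per metric.

## Synthetic phantoms

The generator emulates what matters to the pipeline: a smooth
low-frequency tissue field multiplied by unit-mean Rayleigh speckle (the
first-order model of coherent ultrasound texture), hypoechoic lesions
(interior intensity reduced by a contrast factor, 0.55 by default) shaped
as ellipses with optional radial sinusoidal boundary perturbation, lesion
areas drawn log-uniformly across about two orders of magnitude, a
configurable benign/malignant/normal mix, and both mask conventions
(white-on-black grayscale, and RGB with green = benign / red = malignant).
The lesion scale is found by bisection so the realized foreground count
tracks the requested area within the 15% contract. Everything derives from
one seed, so cohorts are bit-reproducible.

What the phantoms deliberately do not model: acoustic shadowing, posterior
enhancement, beam-profile effects, iso-intense lesion appearance, or
annotation noise. Green tests on phantoms therefore demonstrate that the
machinery (shapes, gradients, protocol, gating, metrics) is correct, not
that clinical-grade accuracy transfers to real ultrasound data.

## Numerical engine and problem sizes

No deep-learning framework is assumed: forward and backward passes run on
a small reverse-mode autodiff engine written for this package, with
convolutions as BLAS products on im2col patch matrices (the gather/scatter
inner loops are compiled C++). Gradients of every operator, and of a whole
tiny N-Unet step, are validated against central finite differences in the
test suite. Batch norm uses batch statistics in training and running
statistics (momentum 0.1) in evaluation; Adam uses the standard
(0.9, 0.999) moments; the learning rate follows cosine annealing from the
initial value to zero across the configured horizon. Training is exactly
resumable from checkpoints, which embed parameters, optimizer state and
the RNG state.

The published full-scale schedule (256x256 inputs, batch 6, 800 epochs,
initial learning rate 1e-5) is the default configuration of
`trainConfig()`, but the package's own verification runs are deliberately
desk-scale: the learning-sanity check memorizes 8 lesion phantoms at
32x32 with an encoder schedule of (8, 16, 32) for 500 steps at learning
rate 1e-3, reaching training Dice >= 0.9 and classification accuracy 1.0,
and the end-to-end pipeline demo uses 32-64 phantoms at 64x64 for a few
epochs. These sizes are the package's chosen study conditions for
verifying correctness properties; they make no claims about benchmark
accuracy, which would require the clinical datasets and full-scale
training.

## Known limitations

* The complexity audit is the only bridge to the published full-scale
  model; accuracy figures from the clinical datasets are out of reach at
  desk scale and are not reproduced.
* The calibrated side-branch and gate widths are one solution consistent
  with the printed budget; other width assignments could match it too.
* The hard CSB gate inherits its documented failure mode: any
  classification false negative erases the segmentation for that image.
* Phantom realism is intentionally limited (see above).
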