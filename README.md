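# nunet

Joint classification and segmentation of breast ultrasound images with the
N-Unet multi-task encoder-decoder, implemented in R with a self-contained
reverse-mode autodiff engine (C++ inner loops for the convolutions).

Breast ultrasound analysis couples two decisions on every image: *is a
lesion present?* (benign and malignant merged against normal) and *where
is it?* (binary segmentation). N-Unet answers both from one shared
encoder:

* **AFF (adaptive feature fusion)** blocks on the encoder — a
  depthwise-separable side branch with squeeze-and-excitation (SE)
  recalibration fused into the main path at every level;
* **CLAE (cross-level attention enhancement)** blocks on the decoder —
  CBAM channel+spatial attention followed by an additive attention gate on
  each skip connection;
* a **512 → 1024 → 2 classification head** on the 8×8 bottleneck;
* **CSB (conditional segmentation boosting)** at inference — the discrete
  decision σ gates the whole segmentation map, Ŝ = (1 − σ)·S, so images
  classified normal produce an empty mask;
* the **AMTL loss** — Focal-BCE (γ = 2, fold-specific class weight
  ω = N_neg/N_pos) and Dice (ε = 1e−5) combined with learnable
  homoscedastic uncertainties,
  L = (1/D) Σᵢ [ Lᵢ/(2σᵢ²) + log σᵢ ], σᵢ initialized at 1.

The default configuration is calibrated to the architecture's published
complexity budget: **8.95 M parameters and 14.74 G** (2 ops per
multiply-accumulate) for a 1×3×256×256 input.

Because the clinical datasets are not required, the package ships a
synthetic phantom generator (speckle-textured tissue, hypoechoic lesions
of controlled area, both mask encodings) that stands in for them in every
test, plus the full protocol: stratified five-fold 6:2:2 splitting with a
leakage guard, training-only augmentation, Adam + cosine annealing, a
metric suite with the empty-mask exclusion rule, and a parameter/MAC
complexity audit.

## Worked example

```r
library(nunet)

# 1. a reproducible phantom cohort: 24 images, 64x64, benign/malignant/normal
co <- generateCohort(24, classMix = c(benign = 0.5, malignant = 0.25,
                                      normal = 0.25),
                     areaRange = c(100, 900), size = 64, seed = 1)

# 2. stratified five-fold 6:2:2 split on category x lesion-size tier
man <- co$manifest
man$area <- sapply(co$samples, lesionAreaA)
split <- makeFolds(man, k = 5, seed = 1)
#> Warning: stratum benign large, benign medium, malignant large, malignant
#> medium has fewer samples than folds; its members are spread without
#> duplication
split
#> SplitAssignment with 5 folds (train/val/test): 14/5/5, 14/5/5, 14/5/5,
#> 15/4/5, 15/5/4

# 3. a reduced model, trained briefly on fold 1
samples <- lapply(co$samples, preprocessEval, targetSize = 32L)
cfg <- modelConfig(encoderChannels = c(8L, 16L, 32L), inputSize = 32L)
f <- split@folds[[1]]
fit <- fitNUnet(samples, f$train, f$val, cfg,
                trainConfig(batchSize = 6L, epochs = 10L, initialLr = 1e-3,
                            seed = 1L))
tail(fit$log[, c("epoch", "lr", "train_total", "val_total")], 2)
#>    epoch           lr train_total val_total
#> 9      9 3.015369e-05   0.2347482 0.2316624
#> 10    10 0.000000e+00   0.1986506 0.2323019

# 4. CSB-gated evaluation on the held-out test list
ids <- sapply(samples, sampleId)
report <- evaluateFold(fit$model, samples[ids %in% f$test])
report
#> MetricsReport over 5 images (1 excluded from segmentation by the empty-mask rule)
#>   classification: acc=1.0000 pre=1.0000 rec=1.0000 f1=1.0000 auc=1.0000
#>   segmentation:   iou=0.1999 dc=0.3226 acc=0.6489 se=0.9799 pc=0.2025

# 5. the complexity audit of the full-size default model
complexityReport(buildNUnet(modelConfig()))
#> ComplexityReport: 8.95 M parameters, 14.74 G (7.3719 GMACs) at 256x256
```

The training log shows the cosine-annealed learning rate reaching zero at
the final epoch. After only ten short epochs the classifier already
separates lesion from normal phantoms perfectly, while the segmentation
overlap is still modest (high sensitivity, low precision: the young model
over-segments) -- the learning-sanity test in the suite shows Dice
climbing above 0.9 when training continues to 500 steps. One normal test
image is excluded from the segmentation averages (its overlap ratios
would be undefined), and AUC is computed from the pre-gate lesion
probabilities. The audit line is the
deterministic architecture-fidelity check: 8.95 M trainable parameters
(including batch-norm affine pairs and the two AMTL uncertainty variables)
and 14.74 G for one 256×256 forward pass.

A command-line front end over the same functions is included at
`inst/cli/nunet.R` (`gen-data`, `split`, `train`, `eval`, `predict`,
`audit`, `run-all`).

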