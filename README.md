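# spineseg

Multi-class semantic segmentation of sagittal lumbar-spine MRI in R.
`spineseg` is aimed at researchers working on automated reading of lumbar
MRI — e.g. for lumbar disc herniation (LDH) work-ups — who need a fully
inspectable, dependency-light implementation of an attention-gated residual
U-Net together with the surrounding pipeline: DICOM conversion, CLAHE
preprocessing, LabelMe polygon annotations, training, evaluation and
clinician-readable overlays. Because clinical MRI cannot be redistributed,
the package ships a seeded synthetic spine-phantom generator that emulates
the geometry and contrast of a sagittal lumbar view (five bright vertebral
bodies `L`, five low-contrast intervertebral discs `LD`, one sacrum `S` on a
dark soft-tissue background), so every stage is exercisable and testable at
desk scale.

## The model

The network is a U-shaped encoder–decoder with three 2×2 max-pool
downsampling stages (one fewer than a conventional Attention U-Net, which is
also provided as a `baseline_attention_unet` configuration with four):

* **Shallow residual block** (first and last layers): main path
  `[conv3×3 → BN → ReLU] × 2`, summed with a 1×1-convolution shortcut
  projection of the input.
* **Deep residual block** (inner layers and bottleneck): two parallel 5×5
  convolution branches (each BN + ReLU) concatenated — doubling the channel
  count — then fused by `conv3×3 → BN → ReLU` and summed with a 1×1
  shortcut.
* **Multilevel attention gate** on every skip connection: with encoder
  features *x* and the coarser decoder gating signal *g*,

      α = σ( conv1×1( ReLU( BN(conv1×1(x)) + BN(conv1×1(Up(g))) ) ) ),
      output = α ⊙ x,   α ∈ [0, 1] per pixel.

* **Hybrid loss**: `L = CE + Dice`, with mean cross-entropy
  `CE = −mean log p(true class)` and squared-denominator soft Dice
  `Dice = 1 − mean_c (2Σ p_c y_c + ε) / (Σ p_c² + Σ y_c² + ε)` over the
  foreground classes.

Evaluation follows the standard confusion-count metrics, in percent:
`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `Dice = 2TP/(2TP+FP+FN)` — the Dice
coefficient being the harmonic mean of P and R.

The network, its reverse-mode autodiff engine and the Adam optimizer are
implemented in the package itself (R with RcppArmadillo convolution
kernels); no external deep-learning framework is required.

## Worked example

```r
library(spineseg)

# ten seeded 64x64 phantoms: eight for training, two for validation
pairs <- lapply(1:10, function(i)
  generate_phantom(phantom_spec(image_size = 64, rng_seed = i,
                                noise_sigma = 6))[c("image", "mask")])

set.seed(11)
model <- build_model(net_config(base_channels = 8))
fit <- train_model(model, pairs[1:8], pairs[9:10],
                   train_config(batch_size = 2, epochs = 200,
                                learning_rate = 1e-3, rng_seed = 5))
print(fit)
#> spineseg_fit: 200 epochs, best epoch 186 (val loss 0.0179)
#>   final val Dice: 98.64%

evaluate_model(fit, pairs[1:8])$report
#>    unit   TP FP FN   P   R Dice
#> 1 image   24  0  0 100 100  100
#> 2 pixel 4551  0  0 100 100  100

mask <- predict(fit, pairs[[9]]$image)       # integer class-ID matrix
write_rgb_png(overlay_mask(pairs[[9]]$image, mask), "overlay.png")
```

The fit log records one training-loss / validation-loss / validation-Dice
row per epoch (`summary(fit)`, `plot(fit)`); the report gives confusion
counts and P/R/Dice at two granularities — per (image, class) presence
verdicts and per pixel. On this deliberately overfittable eight-image task
the network reaches a training-set Dice of 100%; on held-out phantoms of the
same distribution validation Dice is ≈ 98–99%.

A metric sanity check against published lumbar-spine benchmarks is built in:

```r
seg_metrics(list(TP = 743, FP = 35, FN = 43))
#>     P     R  Dice
#> 95.50 94.53 95.01
```

An end-to-end run (phantoms → CLAHE → split → train → evaluate → overlays)
is one call, `run_pipeline(pipeline_config(...))`, and a thin command-line
front end with the same stages ships in `inst/exec/spineseg`.

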