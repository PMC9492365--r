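---
title: "Segmenting the lumbar spine with an attention-gated residual U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the lumbar spine with an attention-gated residual U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spineseg` segments sagittal lumbar-spine MRI into four semantic classes:
background, vertebral bodies (`L`), intervertebral discs (`LD`) and sacrum
(`S`). This vignette explains the model and the design decisions behind the
package, what the synthetic phantoms do and do not show, and the numerical
choices a user may want to revisit.

## The segmentation problem

On T1-weighted sagittal slices the vertebral bodies are bright, the discs
are distinctly darker and low-contrast against soft tissue, and the sacrum
is a wedge below L5. Semantic segmentation assigns one of the four class
IDs to every pixel; all five vertebrae share the single class `L` (the
package does not separate instances). The clinical motivation is faster
reading of lumbar disc herniation studies, where the disc/vertebra
boundaries carry the diagnostic signal.

## Network architecture

The model is a U-shaped encoder–decoder. Its distinguishing choices:

* **Three downsampling stages instead of four.** Each 2×2 stride-2 max-pool
  halves H and W while the channel count doubles. With one fewer level the
  parameter count drops and the bottleneck keeps a coarser-but-larger
  spatial map, which is adequate for the few large structures in this task.
  The conventional four-level layout is retained as the
  `baseline_attention_unet` variant (plain double-3×3-convolution blocks,
  same attention gates), so both can be trained under identical conditions.
* **Two residual block types.** The outermost layers (largest feature maps,
  shallowest semantics) use a *shallow residual block*: two 3×3
  convolutions, each followed by batch normalization and ReLU, plus a 1×1
  convolution shortcut that projects the input to the output width; the
  block output is their sum. All inner layers and the bottleneck use a
  *deep residual block*: two parallel 5×5 convolution branches (BN + ReLU)
  are channel-concatenated — doubling the channels and mixing receptive
  fields — then a 3×3 convolution + BN + ReLU fuses them down to the output
  width, again summed with a 1×1 shortcut. Both blocks reduce exactly to
  their shortcut when the main path is zeroed, the property that eases
  gradient flow; the test suite asserts it.
* **Attention gates on every skip connection.** The gate receives the
  encoder skip features `x` and the decoder's coarser gating signal `g`.
  Both are projected to an intermediate width by 1×1 convolution + BN (`g`
  after a fixed bilinear ×2 upsampling); the branches are combined, passed
  through ReLU, a 1×1 convolution to one channel, and a sigmoid, yielding
  per-pixel coefficients `alpha` in [0, 1] that multiply `x` across all its
  channels. Gating suppresses soft-tissue background in the skips before
  concatenation.
* **Head.** A 1×1 convolution to `n_classes` scores followed by a channel
  softmax; prediction is the per-pixel argmax with ties broken toward the
  lowest class ID.

### Open design points, and how they were fixed

Several architectural details admit more than one reading; the package
fixes each one and exposes the alternative where reasonable:

* *Gate combination.* Descriptions of attention gates variously combine the
  two projected branches by addition or by elementwise product. The package
  defaults to **addition** (the standard additive attention gate this
  architecture extends) and offers `gate_combine = "mul"` for the
  multiplicative reading. Neither is asserted as uniquely correct.
* *Channel widths.* Per-layer widths are not uniquely determined by the
  architecture sketch; the package uses `base_channels` at level 1 doubling
  per level (default 32; the desk-scale tests use 8) — configurable.
* *Upsampling.* Learned 2×2 stride-2 transposed convolution by default
  ("deconvolution"); fixed bilinear ×2 followed by a 1×1 convolution as an
  option.
* *The 5×5 "deep" convolutions* are ordinary (dense) convolutions with a
  larger kernel, not depthwise-separable ones; the text motivating them
  speaks of extracting semantics "at different complexity", which dense
  kernels do.
* *Gate intermediate width* is `max(1, min(Cx, Cg) %/% 2)`; *weight
  initialization* is Kaiming-uniform for convolutions with BN `gamma = 1`,
  `beta = 0`. Both unstated anywhere, both ordinary practice.
* *Padding* is "same" everywhere, so skip connections align without
  cropping.

## The hybrid loss

Training minimizes `w_ce * CE + w_dice * DiceLoss` with unit weights by
default:

* `CE` is the mean over pixels of the negative log-probability of the true
  class. It has well-behaved gradients but is insensitive to class
  imbalance — background dominates a spine image.
* `DiceLoss = 1 − mean_c (2 Σ p_c y_c + ε)/(Σ p_c² + Σ y_c² + ε)` over the
  foreground classes, the squared-denominator soft Dice. It targets overlap
  directly and counteracts the imbalance, at the price of noisier early
  gradients.

The sum stabilizes training relative to Dice alone while keeping the
overlap objective. The relative weighting is not canonical; `w_ce`/`w_dice`
are exposed. A literal per-pixel variant of the Dice term can be derived
from the same machinery but is not the default, because the batch-level
soft Dice is the form in standard use and reproduces the reported behavior
of the hybrid. Numerical guards: `ε = 1e-6` in the Dice ratio, and the CE
log argument is clamped at `1e-12` — with the gradient set to zero on the
clamped (flat) region, which matters for exact finite-difference
verification.

## Evaluation metrics

`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, and `Dice = 2TP/(2TP+FP+FN)`, reported
as percentages. Written this way, Dice is identically the harmonic mean of
P and R, and `seg_metrics()` reproduces the published benchmark rows
shipped in `lumbar_benchmarks()` for every row whose printed metrics are
arithmetically consistent with its own printed counts (8 of the 10 rows;
the two others disagree with their own counts by ≥ 0.01 and are flagged
`consistent = FALSE` — a formula sometimes seen with `TN` in the Dice
denominator reproduces none of the rows and is treated as a misprint of
`TP`). Confusion counts are accumulated at two granularities, because
evaluation units can be whole images or pixels: per (image, class)
*presence verdicts* — positive when the class occurs anywhere in the mask —
and per-pixel class membership. Reports carry both; pixel-level Dice is the
segmentation-quality number.

## The phantom generator

`generate_phantom()` draws a vertically stacked spinal column on a darker
background: superelliptic (rounded-rectangle) vertebrae alternating with
thin elliptic discs along a gentle lordosis-like curve, and a triangular
sacrum wedge at the bottom. Defaults emulate the study conditions of a
sagittal lumbar view: 512×512 canvas (tests use 64–128), 5 vertebrae,
5 discs, 1 sacrum; 8-bit intensity ranges 170–220 for vertebrae, 90–130
for the deliberately low-contrast discs, 40–80 for background; additive
Gaussian noise with `noise_sigma = 8` gray levels by default (6 in the
desk-scale tests, chosen once as a realistic mid-range noise floor).
Every draw is a pure function of `rng_seed`.

The phantoms preserve the *structure* of the segmentation problem — class
inventory, relative contrasts, thin low-contrast discs between bright
vertebrae, touching-class boundaries — but not the *texture* of MRI: no
bias fields, no Rician noise, no pathology, no partial-volume effects.
Tests passing on phantoms therefore demonstrate that the architecture,
losses, training loop and postprocessing are implemented correctly and can
learn this class of geometry; they do not demonstrate clinical-grade
accuracy on hospital data, and the absolute accuracies published for
hospital MRI are out of reach of any desk-scale synthetic run.

"Data enhancement" (augmentation) is implemented as anatomy-preserving
transforms sampled independently with probability 1/2 each: horizontal
flip, rotation uniform in ±10°, intensity scaling in [0.9, 1.1]. Geometric
transforms apply identically to image (bilinear) and mask
(nearest-neighbour, so class IDs are never blended). `expand_dataset()`
keeps all originals and appends augmented copies of uniformly sampled
originals — the expansion factor per original is random, as nothing pins it
down. `split_dataset()` shuffles under a seed and sizes the validation and
test sets as `round(n * ratio)`, with the remainder going to the training
set (the largest bucket, so rounding error lands where it matters least).

## Preprocessing

DICOM slices (single-frame, uncompressed little endian — read by a minimal
reader built into the package, as no installed R package parses DICOM) are
min-max scaled to 8-bit and resized to the working resolution by bilinear
interpolation under the half-pixel-center convention (`src = (dst + 0.5) *
scale − 0.5`), which makes a same-size resize the identity. Global
histogram equalization (`g → round(255 · cdf(g))`) improves contrast but
amplifies noise, so the pipeline uses CLAHE: per-tile histograms (default
8×8 grid, 256 bins) are clipped at `clip_limit` times the uniform bin
height (default 2.0 — the common practice value, as nothing in the problem
fixes it), the excess is redistributed uniformly across bins in a single
pass (no iterative re-clipping; the one-line contract, and the fixed point
of iterating it is nearly identical at these clip values), and pixels are
mapped by bilinear interpolation between the four nearest tile-center
mappings. With `clip_limit = Inf` and one tile, CLAHE reduces to global
equalization exactly — the oracle equivalence the tests assert. The local
binary pattern operator (`lbp()`) is provided as an optional auxiliary
texture channel (8 neighbours at radius 1, replicated borders); it is not
concatenated into the model input by default, since its downstream role is
not fixed by the pipeline description and it is plausibly a labeling aid
rather than a network input.

## Annotations, masks and colors

LabelMe JSON polygons with labels `L`, `LD`, `S` are rasterized by an
even-odd scanline fill evaluated at pixel centers (0-based integer
coordinates, half-open edge rule) **plus** the polygon outline pixels, so
polygons whose vertices lie on integer coordinates include their boundary —
an axis-aligned rectangle from (0,0) to (9,9) covers exactly 100 pixels.
Later shapes overwrite earlier ones (precedence had to be fixed somehow;
"last wins" matches paint-order intuition). On thin structures the
boundary-inclusive fill inflates regions by about one pixel, which is why
phantom-annotation round trips are asserted as high-agreement rather than
exact. Color masks use the fixed scheme red/green/yellow/blue for
background/L/LD/S (exact RGB primaries, since only the color names are
conventional); `colorize_mask()` and `decolorize_mask()` are exact
inverses, and decolorization tolerates small perturbations by
nearest-color assignment. Class-ID masks are written as 8-bit grayscale
PNGs with pixel values 0–3 (the PNG writer available cannot produce
palette-indexed files; both grayscale-ID and RGB color masks are read
back).

## Training loop

`train_model()` runs the standard epoch loop — seeded shuffle, forward,
hybrid loss, backward, Adam step — with one validation pass and one
checkpoint per epoch, tracking the best epoch by validation loss; the
published schedule (batch size 2, 15 epochs, one validation per round,
model preservation each round) is the default configuration. Adam at
learning rate `1e-4` is the default optimizer setting (unstated anywhere;
Adam is the de-facto default for this model family). The desk-scale tests
and the acceptance script raise the rate to `1e-3`, appropriate for the
tiny eight-image phantom task where the default would converge needlessly
slowly. There is no early stopping and no data-loading parallelism:
training on CPU is a bit-reproducible function of data and seed, which the
tests assert. A non-finite loss aborts immediately with the epoch and term
values.

The engine underneath is a small reverse-mode autodiff over `(N, C, H, W)`
arrays: convolutions (im2col + BLAS via RcppArmadillo), transposed 2×2
convolution, 2×2 max-pooling, batch normalization (running statistics for
evaluation mode), bilinear ×2 upsampling, channel concatenation, the gate
multiply, softmax, and the two loss terms. Every operator's backward pass
is verified against central finite differences in the unit tests, as is
the end-to-end gradient of the hybrid loss through the full network.

## Problem sizes used by the tests

The suite trains at sizes chosen to keep the full run comfortably
reproducible on a single CPU: the overfit check uses eight 64×64 phantoms
for 200 epochs with `base_channels = 8` (reaching training Dice 1.00;
about 8 minutes), and the improved-vs-baseline comparison trains both
variants three times for 30 epochs on a common 48×48 split (validation
Dice ≈ 0.98 vs ≈ 0.91 in a representative run). These sizes are the
package's reference desk problem, not a claim about clinical images.

## Known limitations

* The phantom task is far easier than clinical MRI; reported desk-scale
  Dice values do not transfer.
* The engine is CPU-only and sized for small images; 512×512 training
  works but is slow (inference at 512×512 is fine).
* All five vertebrae are one semantic class; no instance labels (L1–L5).
* DICOM support is deliberately minimal: single-frame, uncompressed,
  little endian.
* Image-level confusion counts depend on the presence-verdict rule
  documented above; other rules (e.g. thresholded per-class Dice) would
  give different image-level numbers. Pixel-level metrics are unaffected.
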