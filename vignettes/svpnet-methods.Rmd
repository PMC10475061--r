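---
title: "svpnet: models, phantom world, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svpnet: models, phantom world, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Spontaneous retinal venous pulsations (SVPs) are rhythmic diameter changes
of the central retinal vein, visible on or adjacent to the optic disc and
locked to the cardiac frequency. Their absence is a clinically meaningful
sign (raised intracranial pressure, glaucoma risk), but grading is normally
subjective. `svpnet` classifies SVP presence from a >= 3 s, 30 fps,
disc-centered fundus video in two stages: a per-frame optic-disc
segmentation network, and a video classifier applied to a disc-centered
30-frame 64x64 grayscale clip.

### Optic-disc localizer

The localizer is a U-Net with three substitutions:

- **Depthwise-separable convolutions.** Each spatial kernel acts on one
  channel (`O_i = K_i * I_i`); a pointwise 1x1 convolution mixes channels.
  For `C_in = 4, C_out = 8, k = 3` this costs 68 weights instead of 288.
- **Recurrent-residual blocks.** One depthwise-separable convolution layer
  `g` (+ normalization + ReLU) is applied recurrently with *shared* weights:
  `z0 = g(x)`, `zs = g(x + z(s-1))` for `s = 1..t`, output `x' + zt`. The
  published description ties the recurrence to "a time step of 1", which we
  read as `t = 1` (one forward plus one recurrent application); `t` is
  configurable. When a block changes channel width, `x` is first projected
  by a 1x1 convolution and the recurrence runs at the output width — the
  recurrence formula is otherwise ill-typed; with matched widths the
  projection is the identity and the formula applies literally.
- **Attention gates** on every skip: `alpha = sigmoid(psi(ReLU(W_u u +
  W_g g + b_g)) + b_psi)`, `c = alpha * u`, with one alpha channel per
  pixel. The gating signal `g` is the decoder feature immediately below the
  skip, upsampled to the skip's grid. The printed formula for the gate is
  typographically damaged in the source text; we adopt the standard
  additive-attention reading, which matches the stated activations
  (sigma1 = ReLU, sigma2 = sigmoid).

Decoder upsampling is nearest-neighbour followed by a 1x1 channel-halving
convolution (cheap, no checkerboard artifacts); gated skip and upsampled
decoder feature are concatenated and passed through another
recurrent-residual block; the head is a 1x1 convolution + sigmoid, giving a
full-resolution probability map. Training follows the published protocol:
soft Dice loss (`eps = 1e-6`), RMSprop at learning rate 0.003, batch size 6,
75/20/5 train/validation/test split (floor rounding, remainder to training,
seeded shuffle), model selection by best validation loss. Masks are
thresholded at 0.5 with ties counted as foreground.

### Classifiers

All five architectures share the input contract (30, 64, 64, 1) in [0,1]
and a two-class softmax head, trained with cross-entropy and Adam. Printed
constraints are honored: ConvLSTM kernels 3x3 with tanh activations and
(1,2,2) max pooling + batch normalization after each layer; LRCN
time-distributed 3x3 convolutions with 2x2 max pooling feeding an LSTM;
3D ResNet with 3x3x3 kernels in the stem and residual blocks and 1x1x1
elsewhere; per-architecture learning-rate defaults 0.0003 / 0.0028 / 0.002 /
0.0029 / 0.004 (3D Inception / 3D Dense-ResNet / 3D ResNet / LRCN /
ConvLSTM), batch size 30, 100 epochs.

The ConvLSTM cell is implemented exactly as printed, including the unusual
output-gate peephole on the *current* cell state `C_t`;
`peephole_on_previous = TRUE` restores the conventional `C_{t-1}` form.
Peephole weights are elementwise and state-shaped; the forget-gate bias is
initialized to 1 (a standard trainability default; the source text does not
specify initialization).

Where the source text does not pin down layer counts or widths, two presets
exist. `"paper"` keeps full-scale widths at 64x64 resolution. `"small"`
(used by the test suite) first average-pools the input to 16x16 and uses
narrow stacks. Two further desk-scale deviations in the small presets are
deliberate:

- The three feedforward 3D networks use a **flatten head** instead of global
  average pooling. The pulsation signal lives in a handful of vein-adjacent
  cells; global averaging dilutes it ~100-fold, and at a few hundred
  gradient updates the optimizer never recovers it. A linear head over the
  (15, 8, 8, C) feature block learns the localized motion feature reliably.
  The paper presets keep Global-Average-Pooling as printed.
- The small ConvLSTM averages space per frame before its dense head,
  keeping the 30-step temporal profile that the recurrent states encode.

### Normalization

Batch normalization placement follows the published structure (after each
convolution, before ReLU), but with sample-at-a-time desk-scale training
batch statistics degenerate, so normalization uses the sample's own
per-channel statistics (instance normalization) in both training and
inference. A running-statistics variant was tried and rejected: stale
statistics destabilized the short training runs used here.

## The phantom world

The generator emulates the statistical structure the pipeline needs, not
photorealism:

- a bright elliptical disc (flat intensity 0.85) on a textured background
  (0.45 plus two low-frequency cosine fields of amplitude 0.03),
- 2-4 dark vessel curves of ~5 px width rendered as anti-aliased polylines,
  darkening the frame by the background-vessel contrast so that zero
  contrast renders nothing (this keeps the "flat disc" invariant exact),
- for videos: one straight vertical vein through the disc center whose width
  follows `w(t) = w0 (1 + a sin(2 pi f t / fps))` with `a = 0.3` by default
  ("present") or `a = 0` ("absent"), `f = 1.2 Hz` (a resting cardiac
  frequency), plus two near-horizontal static vessels kept clear of the
  central measurement row,
- i.i.d. Gaussian pixel noise (sd 0.02 by default) clipped to [0,1].

The mask is exactly the analytic ellipse membership set (vessels are not
annotated, matching how public disc datasets are labeled). Everything is a
pure function of (spec, seed); datasets jitter disc center (8% of frame),
radii (±15%), amplitude (±30%), and vein width (±15%) per sample with
disjoint per-sample seeds. The amplitude default 0.3 is a free choice — the
source study reports no amplitudes — roughly between the "nonexistent"
(<15% expansion) and "clinically evident" (>50%) bands it cites.

What the phantom does *not* model: vessel branching, eye motion or
registration error, illumination drift, interlacing, or realistic texture.
A green learnability test therefore establishes that the implementation can
learn and measure what it claims on this stated world — not clinical
performance.

## Numerical and procedural choices

- Coordinates are 0-based (row, col); bounding regions are half-open;
  crops are square-padded (the source does not say; square keeps the resize
  isotropic) with a default margin of 0.25 per side, approximating the
  "within one disc diameter" observation region.
- Per-frame regions are aggregated by coordinate-wise median (robust to
  per-frame jitter); the largest 4-connected component wins within a frame.
- Luminance conversion uses Rec.601 weights (0.299, 0.587, 0.114); resizing
  is bilinear for intensities, nearest-neighbour for masks.
- Dice smoothing `eps = 1e-6`; probability and mask thresholds use `>=`.
- The label mapping is fixed: class 2 of the softmax is "present", and the
  decision rule is `P(present) >= 0.5`.
- Cross-validation shuffles with a seed, splits into folds of size ±1,
  trains a fresh model per fold, and applies 180-degree-rotation
  augmentation *after* splitting, to training folds only — augmented copies
  can never straddle the train/test boundary. The `Ave.` row reports the
  population (n-divisor) standard deviation by default; verified against
  the published per-fold sensitivity column (78, 99, 91, 88, 99 -> 91 ± 8
  with the population divisor, ±9 with the sample divisor). Sample sd is
  available via `sd_type = "sample"`. Mean ROC is the mean of per-fold
  AUCs. Folds are split at the clip level; with two eyes per participant in
  real data this can leak identity across folds — flagged, since the source
  protocol does not say.
- AUC uses the rank formulation (ties count half), equivalent to
  trapezoidal integration over all thresholds.
- Undefined metrics (zero denominators) are reported as `NA`, never as 0.
- The engine differentiates by reverse-mode sweeps over a creation-order
  tape; parameters accumulate gradients across a batch processed sample by
  sample, then one optimizer step applies the batch mean. RMSprop uses
  rho = 0.9, eps = 1e-8; Adam uses (0.9, 0.999) with bias correction.
  He-uniform initialization throughout, seeded per model.

## Interfaces

Images and masks are written as PGM (binary P5 at run time, text P2 for
fixtures) and clips as PGM directories with a JSON manifest; configs are
JSON. PNG and YAML were specified originally, but neither codec package is
part of the guaranteed runtime environment, and PGM/JSON round-trip
bit-exactly with zero dependencies. Checkpoints are JSON parameter dumps
plus a config snapshot; `load_model()` rebuilds the architecture from the
snapshot and restores weights.

## Known limitations

- Sample-at-a-time training makes large batch sizes slow; desk-scale
  presets use small batches (the gradient math is identical).
- `"paper"`-preset training at 64x64 with 100 epochs is computationally
  out of scope for the test suite; the presets are built and
  forward-verified only.
- The smoke-tier learnability thresholds were met with fixed seeds; other
  seeds can fall below them — the tests pin the whole world (data seed,
  init seed, shuffle seed) for reproducibility.
- The phantom's SVP is a global sinusoid; real SVPs show irregular rhythm,
  focal caliber change, and observer-dependent visibility. Multi-tier
  amplitude grading is explicitly out of scope.
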