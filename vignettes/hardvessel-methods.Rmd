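---
title: "Methods: harmonic dense networks for retinal vessel segmentation"
author: "hardvessel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonic dense networks for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Retinal vessel segmentation assigns every pixel of a color fundus
photograph to *vessel* or *background*, restricted to the circular
field of view (FOV) of the camera. The vessel tree is thin (capillaries
approach single-pixel width), low-contrast, and heavily class-imbalanced
(roughly a tenth of FOV pixels are vessel), which is why architectures and
losses tuned for it differ from generic segmentation defaults. Reference
datasets follow the DRIVE conventions: RGB images (565 x 584), a binary
"manual" vessel gold standard, and a binary FOV mask; evaluation is
pixel-wise inside the FOV.

## Model

The network is a U-Net-shaped encoder-decoder with three substitutions.

**Harmonic dense encoder.** Each encoder stage is a *harmonic dense
block*: like a dense block, layer `k` concatenates earlier outputs, but
shortcuts are pruned to layers `k - 2^n` for the `n` with `2^n | k`, and
layers at positions divisible by high powers of two are widened by
`growthRate * multiplier^p` (rounded down to even), `p` the largest such
power. The block output concatenates the last and all odd-indexed layers,
so even-indexed activations can be freed once consumed. `hardBlockLinks()`
and `hardBlockChannels()` expose the rule; both are tested against
exhaustive enumeration. The encoder is a two-conv stride-2 stem (giving
1/4 resolution) followed by four stages (block, 1x1 transition,
2x2 average-pool between stages), producing features at 1/4, 1/8, 1/16
and 1/32.

**Receptive field blocks on the skips.** Each of the three deepest skip
paths passes through a four-branch module (1x1; 1x1 -> 3x3 at dilations 1,
3, 5), concatenated, fused by a 3x3 conv, plus a 1x1 shortcut. The
dilation rates are a design choice (the design we follow shows the module
only schematically); an impulse-response test verifies the dilation-5
branch widens the footprint to at least 11 x 11 versus 3 x 3 for a plain
conv.

**Cascaded partial decoder with multiplicative aggregation.** The 1/4
skip is discarded — the partial-decoder argument: shallow features cost
the most compute and contribute the least semantics. The 1/8, 1/16 and
1/32 streams are reduced to a common width, coarser maps are bilinearly
upsampled (half-pixel centers), each stream is refined by conv+BN+ReLU,
and the streams are fused by progressive element-wise multiplication —
a soft mutual gating that suppresses background activations. The fused
streams are concatenated, transformed by a conv (the `Fcat`/`Ftrans`
steps), added to a 1x1 shortcut of the finest stream (`Fout = Ftrans +
Xskip`), and projected to single-channel logits at 1/8 scale, which are
bilinearly upsampled to the input resolution and passed through a
sigmoid. Both the multiplicative cross-scale fusion and the additive skip
are present because they act at different places: multiplication fuses
across scales, addition closes the refinement residual at the finest
scale.

Four ablation variants are first-class configurations
(`modelConfig(variant = ...)`): `baseline` (plain double-conv stages,
plain 1x1 skips), `hard`, `rfb`, and `full`.

**Default channel plan.** Stem 3->16->16; growth rates (10, 16, 18, 24)
with multiplier 1.7 and (4, 4, 8, 8) layers per block; stage transitions
to (24, 32, 40, 48) channels; decoder width 24. The published design
names its backbone but not its widths, so parameter counts are reported
(`countParameters()`) but never asserted against published tables.
Normalization is batch norm with per-channel affine; activations are
ReLU; convolution weights are He-normal initialized. Inputs whose sides
are not multiples of 32 are zero-padded (centered) internally and the
output cropped back, so 592 x 592 and 1008 x 1008 protocol sizes work
unchanged.

## Loss

With prediction `S` in [0,1] and ground truth `G` in {0,1}, the training
objective is

```
L = lambda1 * L_IoU^w + lambda2 * L_BCE^w,     lambda1 = lambda2 = 0.5
```

where both terms carry per-pixel edge weights
`w = 1 + gamma * |mean31(G) - G|`: the absolute difference between a
pixel's label and the mean of its 31 x 31 neighborhood (a 15-pixel reach
in the four cardinal directions). Interior and far-background pixels get
weight 1; boundary pixels get up to `1 + gamma` (default `gamma = 5`, a
conventional choice — the published description fixes only
proportionality, not the constant). The weighted terms are

```
L_IoU^w = 1 - sum(w S G) / sum(w (S + G - S G))        (soft IoU)
L_BCE^w = sum(w * xent(S, G)) / sum(w)                 (weight-normalized)
```

With `w = 1` these reduce exactly to the plain soft IoU complement and the
mean binary cross-entropy. Near borders the neighborhood mean is taken
over in-bounds pixels only (count-corrected), which keeps `w = 1` exact on
constant masks; a zero-padded policy is available (`border = "zero"`).
`S` is clamped to `[1e-7, 1 - 1e-7]` inside the logs. The "31 x 31 matrix
from a 15-pixel neighborhood in four cardinal directions" is read as the
full square window — a cross-shaped set cannot form a 31 x 31 matrix.
Vectorized losses and the weight map are tested against scalar
double-loop oracles; analytic gradients against finite differences.

## Training protocol

Adam (`beta1 = 0.9`, `beta2 = 0.999`) with a staged learning rate: 0.003
for the first 150 epochs, then 0.0001 (`lrAt()`). Images are min-max
normalized to [0, 1]; optional per-channel 256-bin histogram equalization
(`equalizeImage()`) follows the plain empirical-CDF map. Geometric
normalization is pad-and-crop, not interpolation: results "cropped back"
are only lossless under padding, and padding preserves single-pixel
vessels bit-exactly. Per epoch each training image receives exactly one
augmentation drawn uniformly from {horizontal flip, vertical flip,
contrast, Gaussian noise}; flips move image and masks together, intensity
ops touch the image only. Magnitudes (contrast factor U[0.8, 1.2], noise
sigma U[0.005, 0.03]) are package choices; the protocol we follow names
the menu but not the magnitudes. The 9:1 train/validation split is
deterministic by sorted id. Checkpoints are written every 20 epochs —
"every 20 iterations" is read as epochs, since 20 gradient steps is
roughly one epoch at DRIVE scale, which would make the statement vacuous
— and at the best validation loss (validation accuracy is also logged).
Batch size defaults to 8 at <= 128 px and 2 above.

## The synthetic fundus simulator

The simulator exists so every component is testable without downloads.
It emulates the features that matter to this architecture and loss:
a bright circular FOV disc on dark background, a smooth vignetted,
reddish background field, branching curvilinear trees entering from the
FOV rim with multiplicatively tapering widths, and additive Gaussian
noise. Defaults (one-time choices, stated here): 128 x 128 canvas, 4
trees, depth 5, branch probability 0.3, initial width 4.5 px decaying by
0.88 per generation (terminal widths ~2.4 px), segment length ~9 px,
angle jitter 0.15 rad, bifurcation split +/- pi/6, vessel contrast 0.35
below background, noise sigma 0.03, FOV radius 0.95 of the half-side.
This yields 10-15% vessel density inside the FOV and trunk-to-branch
width ratios comparable to fundus photographs at this scale. Each sample
draws from its own RNG stream derived from `(seed, index)`, so datasets
are bit-reproducible and order-independent. Ground-truth masks are
rasterized without anti-aliasing (a pixel is vessel iff its center lies
within width/2 of a segment), verified against a naive
distance-to-segment oracle.

What the simulator does *not* model: optic disc and fovea, lesions and
exudates, inter-image illumination and pigmentation variability, camera
blur, and the annotation noise of human gold standards. Passing the
synthetic checks therefore demonstrates that the architecture, loss,
optimizer and evaluation pipeline are correct and can learn curvilinear
structure — not that the trained weights transfer to clinical data.

## Problem sizes, numerics and reproducibility

The test suite and the acceptance script run two training experiments at
sizes chosen for a single CPU: a capacity check (4 images, 128 x 128,
300 epochs) and a generalization check (20 training / 10 held-out images,
120 epochs). Bilinear resampling uses half-pixel centers with edge clamp;
average pooling is 2 x 2; batch-norm statistics are biased (1/M) with
momentum 0.1 running averages used at evaluation. All randomness flows
through R's RNG seeded per run; training histories are bit-reproducible
for a fixed seed and thread count.

## Known limitations: resolution of the partial decoder

The decoder emits logits at 1/8 of the input resolution by design and
upsamples them bilinearly. A bilinearly interpolated logit field can
place *straight* boundaries with sub-grid precision, but cannot represent
structure whose scale is below the 8-pixel logit spacing — exactly the
regime of 1-4 px vessels. On the simulator's standard conditions we
measured the *representational ceiling* of this output stage directly,
by optimizing a free 1/8-scale logit map against each ground-truth mask:
the best achievable Dice is ~0.70-0.77 and the best FOV accuracy
~0.88-0.94, and trained models reach this ceiling almost exactly (the
acceptance suite prints both measurements). Threshold-free ranking
quality is less resolution-bound: held-out AUC exceeds 0.95. This is the
package's central known limitation and mirrors the qualitative
observation motivating the design choice it implements — dropping
high-resolution shallow features trades boundary fidelity for speed. A
decoder emitting logits at 1/4 or full resolution would lift the ceiling
but would be a different architecture than the one specified here.

## Degenerate inputs and tie-breaks

Metrics with empty denominators (no positives, empty FOV) return `NaN`
flagged in the report's `undefined` slot rather than erroring; ROC ties
are merged and contribute half-credit, so the trapezoidal AUC equals the
pairwise ranking probability exactly; a constant image equalizes and
normalizes to a constant; masks read from anti-aliased annotation files
binarize at half their dynamic range. The macro-averaged-squared F1
variant that appears in the literature this package follows is exposed as
`f1MacroSquared()` but the standard `2PR/(P+R)` is the default, whose values are
on the scale customarily reported.
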