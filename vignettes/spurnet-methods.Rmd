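---
title: "Two-stage tongue segmentation: model, parameters and design notes"
author: "SpurNet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage tongue segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Tongue inspection in traditional Chinese medicine requires isolating the
tongue region of a photograph from lips, teeth and background before any
color or shape analysis. The hard case is a lip whose color approaches the
tongue's: a purely convolutional segmenter then produces a coarse, wavy
margin, with over-segmentation (tongue label spilling onto the lip) and
under-segmentation (tongue pixels lost at the margin).

SpurNet addresses this in two stages.

**Stage one — UrNet.** A U-shaped encoder-decoder produces per-pixel class
scores for background (0) and tongue (1). The encoding path is a
ResNet18-style residual stack: a 7x7 stride-2 stem, then four stages of
basic residual units (two 3x3 conv + batch norm + ReLU with an identity
shortcut; the first unit of stages 2-4 halves resolution with stride 2 and a
1x1 projection shortcut). The decoder mirrors the encoder with 2x bilinear
upsampling; at each level the same-resolution encoder feature map is
concatenated (the UNet skip connection), followed by two 3x3 conv + BN +
ReLU; a 1x1 convolution emits the two class scores at full resolution. The
coarse mask is the per-pixel argmax, exact ties going to background.

**Stage two — superpixel coverage refinement.** SLIC superpixels are
computed on the input image: localized k-means over joint (color, position)
features with the distance

$$D' = \sqrt{\left(\frac{d_c}{m}\right)^2 + \left(\frac{d_s}{S}\right)^2},$$

where $d_c$ is Euclidean color distance, $d_s$ Euclidean spatial distance,
$S = \sqrt{N^2/K}$ the seed spacing for a side-$N$ image and $K$ requested
blocks, and $m$ the compactness weight. Each seed searches a $2S \times 2S$
window. For every block the *tongue coverage* — the fraction of its pixels
the coarse mask labels tongue — is compared against a threshold $\theta$:
blocks with coverage strictly greater than $\theta$ survive, all others are
cleared to background. Because superpixels adhere to color edges, blocks
straddle the true tongue margin far less than the coarse mask errs there, so
thresholding block coverage snaps the mask to the color boundary.

## Metrics

Four pixel metrics summarize agreement with ground truth, computed from the
confusion tallies TP/FP/FN/TN:

- `PA` $= (TP+TN)/(TP+TN+FP+FN)$ — pixel accuracy;
- `MPA` — mean per-class accuracy;
- `MIoU` $= \frac12\left[\frac{TP}{TP+FP+FN} + \frac{TN}{TN+FN+FP}\right]$;
- `FWIoU` — frequency-weighted IoU.

Two formula dialects are provided. The default `"paper"` mode reproduces the
printed two-class formulas of the study this package implements verbatim:
its MPA averages per-class *precisions* ($TP/(TP+FP)$ and $TN/(TN+FN)$) and
its FWIoU contains only the tongue-class term
$\frac{TP+FN}{\text{total}}\cdot\frac{TP}{TP+FP+FN}$ — which means paper-mode
FWIoU equals the tongue frequency (not 1) even for a perfect prediction. The
`"standard"` mode provides the conventional recall-based MPA and the
frequency-weighted sum of both class IoUs. PA and MIoU agree between modes.
A per-class 0/0 term (class absent in both prediction and truth) is dropped
from averages rather than propagating NaN.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| input side | 256 px | canonical resolution; all images are resized here |
| normalization | $2v/255-1$ | maps 8-bit intensities to $[-1, +1]$ |
| encoder widths | 64/128/256/512 | ResNet18 stage channels, scaled by `widthMultiplier` |
| dropout | 0.6 | bottleneck only, training only |
| optimizer | Adam, lr$_0$ = 1e-3 | pixelwise cross-entropy loss |
| lr decay | 1e-4 | lr $= \mathrm{lr}_0/(1 + \mathrm{decay}\cdot t)$, $t$ = optimizer steps |
| early stopping | patience 10 | stop after 10 epochs without a strictly lower monitored loss |
| augmentation | rot 10°, shifts 0.2, channel shift 0.2, both flips | training only |
| SLIC $K$ | 200 | requested blocks; realized count is $\lfloor N/\lfloor S\rfloor\rfloor^2$ |
| SLIC $m$ | 10 | compactness on the CIELAB scale |
| SLIC pre-smoothing | $\sigma = 1$ px | Gaussian blur before feature extraction (0 disables) |
| SLIC iterations | 10 | with early exit when no label changes |
| $\theta$ | 0.5 | coverage threshold, strict inequality |
| refine mode | retain | keep coarse labels in surviving blocks |

Decisions the source material left open, and how this package resolves
them:

- **Iteration counter of the lr decay** is optimizer steps, not epochs: with
  a decay of 1e-4 the schedule is only meaningful at step granularity.
- **Early stopping monitors the training loss** by default (a validation
  monitor is a flag): the protocol statement names only "the loss".
  "Decrease" is strict; equality does not reset the patience counter.
- **Dropout placement** is the bottleneck: the rate (0.6) is prescribed but
  not the location, and bottleneck dropout is the conventional choice for
  U-shaped encoder-decoders.
- **No pretrained weights**: the encoder is He-initialized, since the
  training protocol begins "initialize weight of network".
- **"Retained" vs "filled" blocks.** Whether a surviving block keeps its
  coarse labels or is set wholly to tongue is genuinely ambiguous; both
  semantics are implemented (`mode = "retain"` / `"fill"`). Retain is the
  default (the literal reading, and conservative: the refined tongue is
  always a subset of the coarse one). Only fill can repair
  under-segmentation; the parameter sweep may select either.
- **SLIC color space** is CIELAB, the canonical choice; raw RGB is a flag
  for ablation. SLIC runs on the raw 8-bit image, not the normalized one.
- **Augmentation fill policy**: pixels exposed by rotation/shift are filled
  with the nearest edge value in the image and with background in the mask,
  so augmentation can never create phantom tongue pixels. The channel shift
  (0.2) is read on the normalized scale; shifts are fractions of the image
  side (the common convention for a bare 0.2).
- **Lip/teeth classes**: annotations are binarized against a single
  positive category ("tongue"); other category names are ignored rather
  than rejected so multi-class label files degrade gracefully.

## Numerical choices and tie-breaks

- SLIC seed grids use spacing $\lfloor S\rfloor$ offset $\lfloor S/2\rfloor$
  from the border; the realized block count can differ from $K$.
- All argmin comparisons break ties toward the lowest seed id, making SLIC
  fully deterministic (it contains no randomness at all).
- Seed perturbation moves each seed to the minimum-gradient pixel of its
  3x3 neighborhood; a seed already at the minimum stays put.
- Pixels covered by no search window (possible only for degenerate seed
  layouts) fall back to the globally nearest seed under $D'$.
- Orphan connectivity fragments are merged into the largest adjacent block;
  block membership is re-read as merges proceed so the final labeling is a
  partition of connected blocks.
- Superpixel features are extracted from a lightly smoothed copy of the
  image ($\sigma = 1$ px Gaussian, configurable). Per-pixel noise otherwise
  drags block boundaries off the true color edge, and coverage
  thresholding only helps where blocks are label-pure: clearing an impure
  majority-background block removes its true tongue pixels. Reference SLIC
  implementations expose the same pre-smoothing control.
- Mask prediction resolves exactly tied class scores to background.
- The network engine stores activations as (pixels x channels) matrices and
  implements convolution as an im2col gather plus a BLAS product; backward
  passes are hand-derived and verified against numerical differentiation in
  the test suite (the only non-smooth points are ReLU kinks).
- Batch-norm running statistics are restored together with the best-epoch
  weights when early stopping rewinds training.

### When does windowed assignment equal exhaustive search?

One SLIC assignment pass restricts each pixel's candidate seeds to those
whose $2S$ windows cover it. This equals brute-force nearest-seed search
over *all* seeds exactly when two premises hold: every pixel is covered by
at least one window, and the color term cannot outweigh the spatial penalty
of leaving a window — any seed outside the window is at $D' > 1$, while the
spatially nearest seed is within $d_s/S \le \sqrt{1/2}$, so it suffices that
the image's color diameter stay below $\approx 0.7\,m$. Natural photographs
at superpixel scale are in this regime; adversarial white-noise images with
small $m$ are not (a far-away seed with a coincidentally matching color can
win the exhaustive search). The equivalence tests therefore draw random
images of moderate contrast (RGB spread 40, CIELAB diameter about 56) and
use $m = 100$, which satisfies the premise provably rather than by luck.

## The synthetic scene generator

Clinical tongue photographs cannot be redistributed, so the test bed is a
generator that emulates their structure with exact ground truth: an
axis-aligned elliptical "tongue" (semi-axes drawn from fractions 0.16-0.26
and 0.20-0.30 of the side, center jittered around the lower image half), a
"lip" band rendered as a partial annulus hugging the upper tongue boundary
at a configurable Euclidean color distance from the tongue mean (default 40;
shrinking this gap reproduces the hard case where segmentation errors
concentrate at the tongue/lip margin), a darker noisy background, and
per-pixel Gaussian texture noise (sd 8). The ground-truth mask is the exact
set of pixel centers inside the ellipse, so a perfect predictor scores
exactly 1.0 and every metric is anchored.

A separate corruption operator emulates coarse-CNN errors on the truth
itself: the mask boundary is displaced by a smooth bounded field (blurred
white noise added to the signed distance transform and re-thresholded,
displacement capped at `boundaryJitterPx`), and small disks get their labels
flipped. This gives refinement experiments a controlled, seedable error
model independent of any trained network. Expected generator behavior that
is deliberately *not* asserted in the unit suite (it needs a dozen full
training runs): a fixed network trained identically should score lower
held-out MIoU as the lip/tongue gap shrinks.

What passing these tests does and does not show: the synthetic scenes share
the clinical data's *structure* (adjacent near-tongue-colored distractor,
smooth boundary, noisy background) but none of its photographic variation —
lighting, pose, teeth, specularity, motion blur. Results on the synthetic
bed validate the implementation and the refinement mechanism, not clinical
performance.

## Problem sizes used for validation

The shipped checks run, by choice, at desk scale: oracle equivalence on
images up to 32x32 with up to 16 seeds; metric oracles on 1000 random 16x16
mask pairs; refinement direction on 50 seeded 256x256 scenes with boundary
jitter 3 px and 5 speckles ($K = 200$, $\theta = 0.5$, retain); sweep
stability over $K \in \{50, 100, 200, 400\}$ on 6 scenes; an overfit run of
a 1/8-width UrNet on 8 scenes at 64x64 for up to 200 epochs (training pixel
accuracy must reach 0.99); and an end-to-end command-line pass (synthesize,
train, predict, refine, evaluate, 2-fold cross-validation) at 64x64. The
acceptance script reports the quantities these computations produce.

## Known limitations

- The network engine is plain R over BLAS: adequate for the width-scaled
  models used in validation and for CPU-scale experiments, not for training
  full-width models on large datasets.
- Paper-mode MPA/FWIoU are faithful to the printed formulas, which are not
  the conventional definitions; comparisons with other software should use
  standard mode.
- Ellipse-plus-annulus scenes cannot measure clinical accuracy (see above).
- Refinement operates at the canonical square resolution; masks for
  non-square originals are produced by nearest-neighbor resize on output.
- `retain` mode can only remove false positives; repairing
  under-segmentation requires `fill` mode, whose benefit depends on block
  purity.
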