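---
title: "Multi-task stereo: joint disparity and instrument segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task stereo: joint disparity and instrument segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Stereo endoscopes see a scene twice from horizontally displaced viewpoints.
After rectification, a scene point imaged at left pixel $(x, y)$ reappears in
the right view at $(x - d, y)$; the horizontal offset $d$ is the *disparity*,
and depth follows as $Z = fB/d$ with focal length $f$ (pixels) and baseline
$B$ (mm). Surgical guidance additionally needs to know *where the
instruments are*, a binary segmentation problem on the same frames. This
package implements a single network that answers both questions at once: a
shared convolutional encoder feeds (i) a cascaded cost-volume disparity head
and (ii) a U-Net-style binary segmentation head. Sharing the encoder means
features are computed once per frame, and — more interestingly — training
the *segmentation* head on monocular labels adapts the shared features and
improves the *disparity* task in a new domain without any stereo
ground truth.

## Architecture

**Shared encoder.** Two variants produce feature pyramids at scales
$S_2 \dots S_6$ (resolutions $1/2 \dots 1/32$ of the input; inputs must be
divisible by 32):

* *lightweight* — five blocks of [3×3 stride-2 conv, batch norm,
  LeakyReLU(0.1), 3×3 conv, batch norm, LeakyReLU(0.1)] with widths
  16, 32, 64, 96, 128. Convolutions feeding batch norm carry no bias (the
  batch-norm shift makes it redundant); with that convention the encoder has
  exactly 469,488 trainable scalars (0.47 M).
* *resnet34* — a standard headless ResNet34; the five taps are the stem
  output (before max-pooling) and the four residual stages, with widths
  64, 64, 128, 256, 512 (21.28 M parameters).

**Disparity head.** Disparity is estimated coarse-to-fine. At the coarsest
scale $S_6$ a *unidirectional* cost volume compares the left feature at $x$
with the right feature at $x - o$ for offsets $o = 0 \dots 10$; with the
maximum disparity configured to 320 px and scale factor 32 this is
$320/32 + 1 = 11$ planes. Costs are the mean over channels of the
element-wise feature product (mean-of-products keeps magnitudes small). At
each finer scale the previous estimate is bilinearly up-sampled, doubled and
touched up by a learned 3×3 conv, used to pre-align (warp) the right
features, and a shallow bidirectional ±2 cost volume is built; a small conv
tower (widths 128, 128, 96, 64, 32, then a bare 1-channel conv) regresses a
residual correction from the cost volume concatenated with the left
features. At full resolution no cost volume is built — tolerating roughly
2 px of vertical rectification error — and a small 2-D hourglass refines the
up-scaled $S_2$ estimate as a residual.

**Segmentation head.** A U-Net decoder ascends $S_6 \to S_2$ with 4×4
stride-2 transposed convolutions (so up-sampled maps exactly match the skip
connections), concatenating the encoder skip at each scale and applying two
3×3 conv/batch-norm/LeakyReLU stages; a final transposed conv and 3×3 conv
produce full-resolution logits. Masks are `probability > 0.5` with a strict
comparison (ties to background).

## Losses

* **Supervised disparity** (pretraining and disparity fine-tuning): each
  pyramid entry is bilinearly up-sampled to full resolution and multiplied
  by its resolution ratio, then compared to ground truth with smooth-L1
  ($0.5w^2$ for $|w|<1$, $|w|-0.5$ otherwise), averaged over valid pixels
  and then over scales. Ground truth above 320 px is outside the search
  range and ignored.
* **Segmentation**: an equal mix of weighted binary cross-entropy (with
  foreground weight $\beta = (1-0.15)/0.15 \approx 5.67$, matching ~15%
  average tool coverage) and soft dice with $\epsilon = 10^{-5}$.
* **Self-supervised stereo** (multi-task phase, applied to the $S_1$ output
  only): the right image is warped to the left view through the predicted
  disparity by a differentiable bilinear sampler, and the loss mixes a
  photometric smooth-L1 term, an SSIM term on 11×11 patches
  ($c_1 = 0.01^2$, $c_2 = 0.03^2$; loss $= (1 - \mathrm{SSIM}_m)/2$), and an
  edge-aware smoothness term on the disparity normalized by 320:
  $\beta_{ss}\,(\alpha_{ss} L_{ph} + (1-\alpha_{ss}) L_{ssim}) +
  (1-\beta_{ss}) L_{smooth}$ with $\alpha_{ss} = 0.9$, $\beta_{ss} = 0.7$.
  Occlusions are deliberately not masked.
* **Multi-task**: $\alpha_{mt} L_{ss\text{-}disp} + (1-\alpha_{mt}) L_{seg}$
  with $\alpha_{mt} = 0.2$.

## Design choices where the design was open

* **Numerical engine.** All layers run on a small reverse-mode autodiff
  engine written in R: convolutions are im2col gathers followed by BLAS
  matrix products, the conv input gradient is the correlation of the
  (zero-stuffed) output gradient with the 180°-rotated kernel, transposed
  convolutions are zero-stuff + pad + conv over the layer's own weights, and
  bilinear resampling is a cached sparse matrix. Every operator is verified
  against central finite differences in the test suite.
* **Normalization of the WBCE.** The printed form of the weighted
  cross-entropy is an unnormalized sum; this implementation divides by the
  pixel count so the term shares the $[0, 1]$ scale of the dice loss and the
  published 0.5/0.5 mix and $\alpha$ coefficients stay scale-balanced — the
  same reasoning that motivates normalizing the disparity in the smoothness
  term.
* **SSIM windows** are uniform 11×11 box windows on the valid interior (the
  original SSIM uses Gaussian weighting; patch averaging is all the loss
  needs).
* **Image gradients** in the smoothness term are forward differences with
  the last row/column dropped, and $\lVert\cdot\rVert$ is the mean of
  absolute channel gradients.
* **Residual initialization.** Every disparity-regressing conv (the tower
  outputs and the hourglass output) is zero-initialized, and the learned
  up-scaling convs start as an exact ×2 identity (center tap 2). A freshly
  built cascade therefore reproduces plain bilinear up-sampling end to end,
  and training only ever adds corrections — this measurably speeds up
  small-scale convergence and removes initialization noise from the $S_1$
  output.
* **Hourglass layout** (unspecified beyond "a 2-D hourglass"): two stride-2
  encoder stages of widths 32 and 64 on the concatenation of the
  range-normalized up-scaled disparity (divided by 320, so it shares the
  image channels' scale) and the left image, one skip connection, two
  transposed-conv up stages, then the zero-initialized regressor. Unlike
  every other stage, the hourglass convs carry biases and no batch norm:
  with per-sample statistics, normalization cancels the locally
  near-constant disparity channel and amplifies its sub-pixel ripples,
  which measurably destabilizes the full-resolution residual on scenes with
  flat disparity. The cost-volume towers keep batch norm throughout.
* **Warping convention:** $d \ge 0$, right column $= x - d$; out-of-image
  samples read as zero; cost-volume planes are ordered by ascending offset.
* **Batch statistics.** The engine forwards one sample at a time, so batch
  norm always normalizes with the current sample's spatial statistics
  (instance-style); training and inference therefore behave identically and
  inference remains a deterministic function of the input. Running averages
  are still maintained (momentum 0.1) and stored in checkpoints. Evaluating
  with stored running averages instead was measurably worse (a systematic
  train/inference mismatch), which motivated this choice.
* **Boundary conventions:** Bad3 and the 10% coverage filter use strict
  inequalities; IoU of two empty masks is 1 (perfect agreement on absence);
  depth conversion marks disparities at or below 0.5 px invalid instead of
  producing unbounded depths.
* **Ground-truth projection:** when two 3-D points project to the same left
  pixel the larger disparity (nearer point) wins; sub-pixel projections
  round to the nearest pixel without splatting.

## Synthetic scenes: what they emulate and what they do not

The generators exist so that every component — warping, cost volumes,
losses, training, metrics — is exercisable end to end with exactly known
answers and no external data.

* `generate_fronto_scene()` builds a smoothed random-dot texture and shifts
  it by a constant disparity; by construction the rectification contract
  holds to machine precision on valid pixels. Pure white noise would alias
  under sub-pixel resampling, hence the small Gaussian blur.
* `generate_smooth_scene()` samples a clipped sum of random Gaussian bumps
  as the disparity field, synthesizes the *left* view by resampling a
  random texture through it, and marks occlusions with a forward z-buffer
  over right-image columns (nearest disparity wins).
* `generate_instrument_mask()` draws border-entering capsules whose
  proportions were calibrated once so two tools cover on average ~15% of
  the frame — the class-balance statistic behind the WBCE weight. Measured
  over seeds 0–199 at 256×320 the mean coverage is ≈ 0.12–0.13, inside the
  0.10–0.20 acceptance band.

These scenes are fronto-parallel or smoothly varying, Lambertian,
noise-free and perfectly rectified. Passing tests on them demonstrates that
the machinery (matching, gradients, losses, training dynamics) is correct;
it says nothing about robustness to specularities, smoke, fluid, occlusion
boundaries of thin instruments, calibration error or time-desynchronized
stereo channels — all present in real endoscopy.

## Training phases and small-scale experiments

`run_phase()` implements the published phase structure: *pretrain*
(disparity supervision at all scales, segmentation head absent or frozen),
*multitask* ($S_1$-only self-supervision plus supervised segmentation),
and single-task fine-tuning that leaves the other head untouched. AdamW
($\beta_1 = 0.9$, $\beta_2 = 0.999$, weight decay $10^{-4}$) with either a
one-cycle schedule (30% linear warm-up, cosine decay) or a constant rate;
one master seed drives initialization, augmentation and data order.
Augmentation applies a shared random crop, a vertical flip with
probability 0.5 (rows stay aligned so rectification survives; disparity
values are unchanged), and per-channel color normalization.

The package's desk-scale stand-ins for the published experiments, run by
`scripts/acceptance.R` and the test suite, use a width-reduced lightweight
model (`width_scale = 0.25`, i.e. encoder widths 4–32) on 64×64 fronto
scenes with shifts 4–28 px: 200 training scenes, 20 held-out scenes,
7 epochs of one-cycle AdamW (peak 1e-2) at batch size 1 (1,400 steps),
without flip augmentation (flips only add gradient variance on these
symmetric scenes). This configuration recovers held-out EPE below 1 px in a
few CPU-minutes. The segmentation stand-in overfits 5 generated masks to
IoU > 0.95 with 250 one-cycle epochs at `width_scale = 0.4`. Problem sizes
were chosen as the smallest at which the cascade's coarse-to-fine structure
is still exercised at all six scales.

## Known limitations

* The engine is single-threaded CPU R; it is meant for correctness,
  experimentation and small-scale study, not for 1280×1024 real-time
  inference.
* Batch-norm statistics are per-sample (batch size 1 per forward); large-
  batch statistics would differ slightly.
* `multitask` self-supervision shares the known failure modes of
  photometric losses: occlusions and repeated texture are not handled.
* ImageNet-pretrained ResNet34 weights are not shipped; `load_checkpoint()`
  can ingest converted weights but random initialization is the default.
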