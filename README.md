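# surgstereo

Joint stereo disparity estimation and binary surgical-instrument
segmentation for rectified endoscopic image pairs, in pure R.

## What this package is for

Stereo endoscopes image the surgical field from two horizontally displaced
viewpoints. After rectification, a scene point seen at left pixel
`(x, y)` appears in the right image at `(x − d, y)`; the disparity `d`
gives metric depth through `Z = f·B / d` (focal length `f` in pixels,
baseline `B` in mm). Intra-operative guidance needs both a dense disparity
map and a mask of the instruments, at video rate — which motivates a
*multi-task* network: one shared convolutional encoder (lightweight
0.47 M-parameter pyramid or ResNet34, 21.28 M) feeding

* a **cascaded cost-volume disparity head** — coarse-to-fine matching over
  scales 1/32 … 1/2 with shallow ±2 cost volumes after warp pre-alignment
  (11 planes at the coarsest scale for a 320 px search range), plus a
  full-resolution hourglass refinement, and
* a **U-Net segmentation head** — transposed-conv decoder with skip
  connections, binary masks at `probability > 0.5`.

The package implements the heads, every training objective (multi-scale
supervised smooth-L1 disparity loss; weighted BCE + soft-dice segmentation
loss; self-supervised photometric/SSIM/edge-aware-smoothness stereo loss;
the α-weighted multi-task combination), the phased training schemes,
evaluation metrics (EPE, Bad3, depth MAE in mm, IoU, the 10% coverage
rule), disparity ground-truth synthesis from 3-D point maps, and synthetic
scene generators that make all of it testable without any external
dataset. Everything runs on a compact reverse-mode autodiff engine written
in R (im2col + BLAS convolutions), finite-difference-verified in the test
suite — so the package is also a readable, fully-checked reference for how
cascade stereo networks work.

## Worked example

Generate a synthetic rectified pair with known disparity, run an untrained
tiny model, train it briefly on similar scenes, and evaluate:

```r
library(surgstereo)

scene <- generate_fronto_scene(height = 64, width = 64, shift = 12, seed = 1)
scene
#> <stereo_sample 64x64, disparity: [12.00, 12.00] px, mask: absent>

# the generator satisfies the rectification contract exactly:
rec <- warp_right_to_left(scene$right, scene$disparity)
mean(abs(rec - scene$left)[array(scene$valid, dim(scene$left))])
#> [1] 0

model <- model_factory("lightweight", heads = "disparity",
                       width_scale = 0.25, seed = 1)
set.seed(2)
train <- lapply(1:40, function(i)
  generate_fronto_scene(64, 64, runif(1, 4, 28), seed = i))
cfg <- train_config("pretrain", epochs = 4, batch_size = 1,
                    lr_schedule = "one_cycle", max_lr = 5e-3,
                    norm_mean = rep(0.5, 3), norm_std = rep(0.5, 3))
fit <- run_phase(model, train, cfg)

left  <- normalize_image(scene$left,  rep(0.5, 3), rep(0.5, 3))
right <- normalize_image(scene$right, rep(0.5, 3), rep(0.5, 3))
pyr <- predict_disparity(model, left, right)
epe(pyr$disparity[[1]], scene$disparity, scene$valid)   # px error, lower = better
#> [1] 0.6915424
bad3(pyr$disparity[[1]], scene$disparity, scene$valid)  # % pixels off by > 3 px
#> [1] 0.2704327
```

So after a couple of CPU-minutes on 40 scenes the model estimates the
12-pixel shift to within 0.7 px on average, with 0.3% of pixels off by more
than 3 px (`experiment_disparity_recovery()` runs the full version of this
study: 200 scenes, 7 epochs, held-out evaluation). Depth conversion and
segmentation follow the same pattern:

```r
rig <- camera_rig(focal_px = 1000, baseline_mm = 5)
disparity_to_depth(matrix(50, 2, 2), rig)$depth[1, 1]
#> [1] 100      # mm

seg_model <- model_factory("lightweight", heads = "segmentation",
                           width_scale = 0.25, seed = 1)
mask <- predict_mask(seg_model, left)$mask       # H x W logical
```

A thin command-line front end ships in `inst/cli/surgstereo`
(subcommands `synth`, `infer`, `evaluate`, `train`, `prep`).

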