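# fibermap

Distance-map regression for fiber micrographs, in R.

Measuring the diameter of animal and synthetic textile fibers from optical
micrographs is how fiber is graded and priced, and it is hard exactly where
it matters: thin, curved fibers that touch and cross. `fibermap` trains a
convolutional encoder–decoder to regress, from an RGB micrograph `A`, its
Euclidean distance map `B_D` — the image whose value at each fiber pixel is
the distance to the nearest background pixel, `B_D = EDT(B)` with
`EDT(x1, y1) = min over background (x2, y2) of sqrt((x1−x2)² + (y1−y2)²)`.
A predicted map `B̂_D = f(A)` separates individual fibers even at contacts,
and its medial-ridge values are fiber half-widths, so per-fiber diameters
follow directly.

The package provides the full loop:

- a **simulator** of realistic fiber micrographs (μ-randomness carrier
  lines — perpendicular offset `d`, angle `α` from the image centre —
  bent into sinusoids, per-fiber gray levels, per-pixel and global Gaussian
  noise) with exact ground-truth masks and diameters;
- exact **Euclidean distance-transform labels** (lower-envelope algorithm,
  verified against an all-pairs oracle);
- two **regression architectures** — a U-Net, and a coordinate-convolution
  variant with residual squeeze-excitation blocks, csSE gating and four
  fused side outputs — trained with **L1, L2 or smooth-L1** loss
  (`0.5x²` for `|x| < 1`, `|x| − 0.5` otherwise) under Adam, LR drop after
  10 epochs, early stopping on a validation split;
- the **G1–G4 evaluation protocol** (real/synthetic × train/test groups,
  default sizes 43/11/43/11, digest-verified disjointness) reporting MAE,
  MSE and NRMSE;
- **diameter morphometry**: segmentation, Zhang–Suen ridge extraction and
  the calibrated estimate `d̂ = 2·q0.9(ridge radii) − 0.2` px.

The CNN engine (convolutions, pooling, transposed convolutions, SE/csSE
blocks, backprop, Adam) is implemented in the package itself over
Rcpp/RcppArmadillo, and every layer's gradient is tested against finite
differences.

## Worked example

A desk-scale study (64×64 canvas at the default fiber density, reduced-width
U-Net) that runs in about two minutes on one CPU:

```r
library(fibermap)

cfg <- simulation_config(height = 64, width = 64,
                         fiber_count_range = c(1, 5))
train <- generate_dataset(cfg, 43, seed = 1)
test  <- generate_dataset(cfg, 11, seed = 2)

fit <- distreg(train, architecture = "unet", loss = "smooth_l1",
               base_channels = 8, depth = 3,
               control = train_config(max_epochs = 30))
print(fit)
#> Distance-map regression (unet, smooth_l1 loss)
#>   trained on 43 images for 30 epochs (best epoch 29)
#>   best validation loss: 0.00490
#>   label space: normalized (scale 5.0 px)

evaluate(fit, lapply(test, function(s)
  list(image = s$image, label = make_label(s))))
#>    n        mae        mse    nrmse
#> 1 11 0.05446146 0.01131108 0.110282
```

The held-out MAE of 0.054 on normalized maps means the predicted distance
values are off by ~0.05 × 5 px ≈ a quarter pixel on average; an all-zero
baseline scores MAE ≈ 0.12, so the model is learning the map, not the
background. Diameters measured from an exact map recover the drawn
thickness to within a pixel:

```r
cfg1 <- simulation_config(fiber_count_range = c(1, 1),
                          amplitude_frac_range = c(0, 0),
                          pixel_noise_sigma = 0, global_noise_sigma = 0)
s <- compose_micrograph(cfg1, seed = 10)
measure_fibers(euclidean_distance_transform(s$mask))$per_fiber[[1]]$diameter_px
#> [1] 7.8     # drawn diameter: 8 px
```

A thin command-line front end wraps the same functions
(`inst/cli/fibermap.R`: `simulate`, `make-labels`, `train`, `predict`,
`evaluate`, `grid`, `measure`), writing a reproducibility manifest beside
every output.

See the vignette (`vignettes/distance-map-regression.Rmd`) for the model,
its assumptions, the calibration of the rasterizer and diameter estimator,
and known limitations.

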