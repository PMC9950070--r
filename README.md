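# rbcmorph

Automated morphology analysis of stored red blood cells (RBCs) from
bright-field microscopy, for blood-storage and transfusion-medicine
research.

During refrigerated storage RBCs undergo the echinocytic transformation:
smooth biconcave **discocytes (D)** grow spicules through three
**echinocyte** stages (**E1–E3**), shed surface area to become
**sphero-echinocytes (SE)** and finally **spherocytes (S)**; the cup-shaped
**stomatocyte (ST)** lies off this axis. The distribution of a unit's cells
over these seven classes is a quantitative marker of the storage lesion,
but manual scoring is slow and subjective. `rbcmorph` implements the full
analysis pipeline as a tested, tidyverse-native R package:

* **Segmentation** — adaptive thresholding (exact local median/mean/
  Gaussian over a `2⌊dim/16⌋+1` window), hole filling, erosion/dilation
  cleanup (disk radius 6), watershed splitting of touching cells (H-minima
  scalar 1), and blob analysis (area, sub-pixel centroid, bounding box,
  100 px² floor); plus a two-stage well/cell pathway with a pluggable
  per-pixel classifier and the focal Tversky loss
  `(1 − TP/(TP + 0.7·FP + 0.3·FN))^0.75`.
* **Classification** — a heterogeneous ensemble of independently trained
  members combined by unweighted softmax averaging
  (`p̄ = (1/M) Σ p_m`, label = argmax `p̄`), trained with the standard
  recipe (SGD, momentum 0.9, lr 3·10⁻⁴, L2 0.005, minibatches 10–32,
  holdout early stopping with checkpoints; minority oversampling +
  cross-entropy for one member, focal loss `−α(1−p_t)^γ log p_t` with
  α = 0.25, γ = 2 for the rest).
* **Calibration** — reliability diagrams, ECE/MCE, confusion matrices with
  precision/recall margins, off-by-one error structure, noise-robustness
  curves.
* **Tracking** — per-cell constant-velocity Kalman filter (initial
  variances 200/50, motion noise [100, 25], measurement variance 100) with
  Hungarian assignment under a non-assignment cost of 20, lifecycle pruning
  (>50 invisible frames, or age <8 with <30% visibility), and shape-change
  detection at the 10-minute mark via a 100-frame moving average.
* **Morphometry** — effective diameter `2√(area/π)·µm/px`, per-class
  summaries with bias-corrected bootstrap 95% CIs (10,000 replicates),
  Kruskal–Wallis + Bonferroni-adjusted pairwise t-tests, Cohen's d, and the
  common-language effect-size matrix `Φ((µ₁−µ₂)/√(σ₁²+σ₂²))`.
* **Synthetic fixtures** — a seeded scene generator (seven separable shape
  classes, illumination gradients, Gaussian/speckle noise, touching clumps,
  microfluidic wells, constant-velocity motion) with exact ground truth, so
  the whole pipeline is testable without microscope data.

## Worked example

```r
library(rbcmorph)
library(dplyr)

# 1. train an ensemble on synthetic crops (200 per class)
crops    <- render_crop_set(n_per_class = 200, seed = 42)
ensemble <- train_ensemble(crops, cfg = train_config(seed = 42))
glance(ensemble)
#> # A tibble: 4 × 6
#>   member        hidden imbalance  holdout_accuracy best_epoch epochs_run
#>   <chr>          <dbl> <chr>                 <dbl>      <int>      <int>
#> 1 mlp-wide          24 oversample            0.964         54         64
#> 2 mlp-compact       12 focal_loss            0.929         91        101
#> 3 softmax-polar      0 focal_loss            1              1         20
#> 4 softmax-grid       0 focal_loss            0.986         16         26

# 2. segment and classify one frame
frame      <- render_scene(random_scene(25, c(640, 640), seed = 7))
detections <- segment_frame(frame$image) |>
  classify_crops(image = frame$image, ensemble = ensemble)
count(detections, predicted)
#> # A tibble: 6 × 2
#>   predicted     n
#>   <fct>     <int>
#> 1 E1            5
#> 2 E2            5
#> 3 E3            5
#> 4 SE            2
#> 5 S             2
#> 6 ST            6

# 3. per-class effective-diameter morphometry
detections |>
  mutate(class    = predicted,
         diameter = effective_diameter(area, um_per_px = 0.195)) |>
  class_diameter_stats(B = 2000, seed = 1) |>
  select(class, n, mean, sd, mean_lo, mean_hi)
#> # A tibble: 6 × 6
#>   class     n  mean    sd mean_lo mean_hi
#>   <chr> <int> <dbl> <dbl>   <dbl>   <dbl>
#> 1 E1        5  7.72 0.115    7.65    7.82
#> 2 E2        5  6.31 0.169    6.18    6.44
#> 3 E3        5  5.35 0.356    5.14    5.67
#> 4 SE        2  5.84 0.270    5.64    5.84
#> 5 S         2  5.78 0.225    5.62    5.78
#> 6 ST        6  7.02 0.119    6.93    7.10

# 4. probability that a random SE cell out-sizes a random S cell,
#    from the bundled published reference distributions
round(100 * cl_matrix(reference_diameter_stats())["SE", "S"], 2)
#> [1] 55.17
```

All 25 cells of the frame are detected, and the diameter summaries track the class ordering (echinocyte stages shrinking from E1 to the spherocyte). This small demonstration ensemble folds the frame's discocytes into E1 — exactly the neighbouring pair whose diameter distributions overlap almost completely — while the 500-crop-per-class ensembles used by the test suite separate all seven classes. Diameters of heavily spiculated classes (E3) describe the cleaned silhouette, which is slightly smaller than the spicule-tip envelope. The final number is the common-language effect size: a randomly drawn sphero-echinocyte has a 55.17% chance of being larger than a randomly drawn spherocyte — a nearly even coin toss, which is why diameter alone cannot separate neighbouring morphology classes.

Longitudinal well recordings are handled the same way: `render_sequence()`
or your own frame stack, `track_sequence()` for persistent identities, and
`detect_shape_change()` for per-cell class transitions at the 10-minute
mark. `plot_reliability()`, `autoplot()` on a confusion matrix,
`plot_diameter_histograms()` and `plot_cl_matrix()` give the standard
figures; a thin command-line front end lives in `inst/cli/rbc.R`.

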