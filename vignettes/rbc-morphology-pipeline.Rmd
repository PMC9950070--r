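---
title: "Methods: segmentation, ensemble classification, tracking and morphometry of stored red blood cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, ensemble classification, tracking and morphometry of stored red blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Red blood cells deteriorate during refrigerated storage. The most visible
symptom is the echinocytic transformation: the smooth biconcave discocyte (D)
grows spicules through three echinocyte stages (E1–E3), loses membrane
surface area to become a sphero-echinocyte (SE) and finally a smooth rigid
spherocyte (S); the cup-shaped stomatocyte (ST) sits outside this axis. The
distribution of a unit's cells over these seven classes is an integrative
marker of storage quality, but manual scoring of a few hundred cells per
sample is tedious and noisy. `rbcmorph` implements an automated pipeline for
bright-field images of such cells — segmentation, seven-class classification
by an ensemble of independently trained members, per-cell tracking through
time, and effective-diameter morphometry — together with a fully
ground-truthed synthetic scene generator so that every stage is testable
without microscope data.

# Segmentation

Frames show dark cells on a bright, slightly shaded background. The
threshold pathway is:

1. **Adaptive thresholding.** Each pixel is compared against a local central
   tendency (median by default; mean and Gaussian-weighted mean available)
   over a rectangular window whose default side is, per dimension,
   `2 * floor(dim / 16) + 1` — 161 × 129 for a 1280 × 1024 frame. A pixel is
   foreground iff it is strictly below its local statistic minus a
   sensitivity offset. The local median is computed exactly (sliding-window
   histogram over 256 intensity levels, replicate-padded borders, lower
   median) in compiled code; the comparison is made on the same quantised
   grid. The default sensitivity is 0.05 intensity units: a strict
   comparison at offset zero turns half of any background — shading
   staircase or sensor noise — into foreground, which then percolates and
   survives hole filling; 0.05 is about two standard deviations of the
   generator's default sensor noise at this contrast and far above one
   quantisation level, while the steep cell boundary (full contrast ~0.5
   over ~1.5 px) loses only a fraction of a pixel. A flat field yields an
   empty mask at any offset.
2. **Cleanup.** Holes are filled — including holes open to a single image
   border, via the one-sided padding trick (a hole touching two borders is
   left open; such regions are not closed cell interiors) — and the mask is
   eroded then dilated with a disk of radius 6 px, which removes specks
   smaller than the element.
3. **Watershed splitting.** The watershed transform of the distance map
   (equivalently, flooding the negative distance transform) with H-minima
   suppression scalar 1 separates touching cells. Ridge pixels between
   distinct catchment basins are set to background; the higher-labelled side
   of every inter-object adjacency (including diagonal adjacency) is
   removed, so split components can never rejoin under the package's
   8-connected component convention.
4. **Blob analysis.** One blob per 8-connected component with area ≥ 100 px²
   (the conventional whole-cell floor at this scale): area, sub-pixel
   centroid, half-open bounding box `(x, y, w, h)` in 0-based coordinates
   (x right, y down; add 1 to convert to 1-based conventions).

Connectivity is one consistent pair throughout: 8-connected components,
watershed ridges that also separate diagonals. Mask resizing uses bilinear
interpolation with re-binarisation at 0.5.

For well-array images the two-stage pathway runs a pluggable per-pixel
classifier twice: wells are found at half scale (mask upscaled, opened with
a radius-3 disk, blob-analysed into boxes), then each well is cropped,
padded to 170 × 170, resized to 224 × 224, pixel-classified, mapped back
through the same geometry, opened (radius 3), dilated (radius 2), watershed
split and blob-analysed with the same 100 px² floor. The classifier is a
contract — `label(image)` returning a same-shape logical raster — so any
semantic-segmentation model can be plugged in. The bundled default is a
logistic model over intensity and multi-scale local mean/dispersion
features whose binarisation threshold is chosen to minimise the focal
Tversky loss (`TI = TP / (TP + 0.7·FP + 0.3·FN)`, `loss = (1 − TI)^0.75`)
on the training pairs; the α/β convention (α weights false positives) is
recorded here because the loss is usually cited without a formula, and all
three hyperparameters are exposed.

# Classification

Each segmented cell is cut out in a fixed-size window (64 px by default)
centred on its centroid — not a bounding-box-proportional crop: absolute
cell size is one of the class-defining features of this pipeline (a
spherocyte is a small smooth disc, a discocyte a large one), and a crop
that scales with the bounding box would normalise exactly that signal away.
Pixels belonging to other segmented cells inside the window, dilated by a
few pixels to cover their sub-threshold soft edge, are blanked to the
window's background median so each cell is classified individually. The
window is then upscaled to 227 × 227 and contrast-normalised against the
border-median background into positive "darkness" values. Members of the
ensemble are compact one-hidden-layer softmax networks over two feature
families computed from that standardized crop:

* a downsampled pixel grid (appearance: size, pallor shape, overall
  darkness), and
* a polar profile centred on the darkness centroid, bilinearly
  interpolated: per-annulus angular means and SDs, plus the half-maximum
  boundary radius per angle with its Fourier amplitude spectrum. Spicule
  count appears directly as a spectral peak; the per-sample spectral floor
  (median amplitude) is subtracted from the spectrum and kept as a separate
  feature, so shallow-spicule detection does not depend on the image noise
  level; centring on the centroid keeps off-centre crops from masquerading
  as spiculated.

Four members differ in feature resolution and hidden width (`mlp-wide`,
`mlp-compact`, `softmax-polar`, `softmax-grid`), which preserves the
heterogeneity that makes unweighted averaging useful. One member handles
class imbalance by random minority oversampling with a cross-entropy loss;
the other three train on the imbalanced set with the focal loss
`−α(1−p_t)^γ log p_t`, α = 0.25, γ = 2. Training is minibatch stochastic
gradient descent with momentum 0.9, initial learning rate 3 × 10⁻⁴, L2
coefficient 0.005, minibatches of 32 shuffled every epoch, and holdout-based
early stopping with checkpoints (best-holdout weights retained; patience 10
evaluations, evaluated every epoch, with runs capped at 300 epochs and a
20-epoch minimum before stopping). Augmentation ranges (±100 px
translation, 0–360° rotation, 75–130% scaling, background-masked
duplicates) are implemented and exposed but off by default during member
training: the synthetic generator already randomises pose, scale and
illumination, and the polar features are computed in a translation-corrected
frame.

Ensemble prediction is the unweighted element-wise mean of the members'
softmax vectors; the label is the argmax of the mean with ties broken by
canonical class order (D, E1, E2, E3, SE, S, ST) for determinism. Taking
the argmax of the mean is identical to taking the highest score in the
unweighted average. Longitudinal score histories are smoothed with a
100-frame moving average; histories shorter than the window average
whatever is available (warm-up behaviour is otherwise unspecified), and
absent-frame gap markers are excluded from the mean.

# Calibration diagnostics

Reliability diagrams use 10 equal-width confidence bins on [0, 1],
right-closed except the first (so a confidence of exactly 1.0 falls in the
last bin); the bin count is configurable because published diagrams rarely
state their edges. Confidence is the maximum averaged softmax probability.
ECE is the count-weighted mean absolute gap between bin accuracy and bin
confidence; MCE is the maximum gap over non-empty bins (empty bins carry no
information and would make the maximum undefined). Confusion matrices carry
per-class precision, recall, false-discovery and false-negative margins,
with overall accuracy = trace/total. The off-by-one error fraction treats
D–E1–E2–E3–SE–S as an ordinal axis — the storage transformation is a
continuum discretised into classes, so most residual errors land on a
neighbouring stage — and treats ST as non-ordinal: errors involving ST are
never "adjacent".

# Tracking

Each cell carries a constant-velocity Kalman filter on state (x, y, vx, vy)
with dt = 1 frame, initial covariance diag(200, 200, 50, 50), process noise
assembled from the motion-noise pair [100, 25] as diag(100, 100, 25, 25)
(the pair is conventionally given per block; the diagonal layout is the
standard construction), and measurement variance 100. Frame-to-frame
association minimises total Euclidean distance between predicted and
detected centroids under the padded-matrix Hungarian formulation: leaving a
track unassigned costs 20 and leaving a detection unassigned costs 20, so a
lone pairing is accepted up to cost 40. The solver is an O(n³)
shortest-augmenting-path implementation validated against brute-force
enumeration. Track lifecycle: assigned tracks append centroid and score
history and reset their invisibility counter; unassigned tracks gain an
explicit absent marker (histories stay frame-aligned) and increment their
invisibility counter; unassigned detections open new tracks with globally
monotone, never-reused ids. Age increments for every track each frame —
assigned or not — so "visible fraction" is total_visible/age. A track is
deleted iff invisible for more than 50 consecutive frames, or younger than
8 frames with under 30% visibility.

Shape-change detection compares the modal smoothed class over an initial
window (default 100 frames; the "from" class) with the smoothed class at the
10-minute mark (600 s at 1 fps, window 100). Tracks not spanning the mark
are flagged not evaluable rather than guessed.

# Morphometry

The effective diameter of a segmented cell is the equivalent-circle
diameter `2·sqrt(area/π)·um_per_px`; no calibration is published for the
source imaging systems, so µm/px is always an explicit parameter (default
0.195, which makes a 7.8 µm discocyte ~40 px across). Distributions are
summarised per class by n, mean ± SD, median, IQR, mean/median absolute
deviations, and 95% confidence intervals from the bias-corrected (BC, not
BCa — no acceleration term is used) percentile bootstrap with 10,000
replicates: `z0 = Φ⁻¹(#{θ*_b < θ̂}/B)`, endpoints at the bootstrap
quantiles `Φ(2z0 ± z_{α/2})` (type-6 empirical quantiles). Constant samples
yield the degenerate interval with a flag. The same BC procedure is applied
to mean, SD, median and IQR alike. Hypothesis testing is a Kruskal–Wallis
omnibus plus all pairwise Welch two-sample t-tests with Bonferroni factor
m = C(k, 2) = 21 for seven classes (the adjustment multiplicity is stated
here because it is often left implicit). Effect sizes are Cohen's d with
(n−1)-weighted pooled SD and the common-language effect size
`Φ((μ₁−μ₂)/√(σ₁²+σ₂²))`, assembled into the 7 × 7 matrix with diagonal 0.5
and `M + Mᵀ = 1`.

The low-resolution cleaning filter is a transparent rule chain — physical
diameter bounds [4, 10] µm, a per-class 3 × IQR fence about the class
median, optional aspect-ratio and solidity screens — with every removal
tagged by the rule that fired (first match wins). The high-resolution
good/bad crop filter is a pluggable binary predicate with a pass-through
default and a per-crop decision log.

The bundled `reference_diameter_stats()` table carries published per-class
effective-diameter summaries for roughly 1.29 million stored cells; it is
used as an input for effect-size computations and for parameterising
synthetic fixtures, never recomputed.

# The synthetic generator

`render_scene()` draws dark cells with a smooth radial profile on a bright
background: class-specific base radius (ordered D ≈ E1 > E2 > ST > E3 >
SE ≈ S, radii derived from the reference diameter table at the default
pixel scale), sinusoidal boundary spicules (count 0 for D/ST, rising 6 →
20 through E1–E3, 26 shallow ones for SE, none for S), a central pallor for
disc-like classes and an offset slit-like pallor for the stomatocyte.
Illumination gradients are low-order polynomial shading (enough to defeat a
global threshold), noise is additive Gaussian or multiplicative speckle
`x·(1+u)` with zero-mean normal `u` of stated variance, and everything is
clipped to [0, 1]. The two generator entry points share one imaging
condition: training crop sets and benchmark scenes both default to mild
sensor noise (variance 5 × 10⁻⁴) and slight illumination variation
(gradients around 0.02), as members trained at one condition should be
evaluated at the same condition. Sequences move cells at constant velocity
plus Gaussian positional jitter; a cell whose centre leaves the frame stays
absent.
Well scenes draw darker rectangular rims and require every cell to sit
inside a well. Fixed seeds make every render byte-identical, and the RNG
state of the caller is never disturbed.

What the generator does **not** emulate: optics (no point-spread function,
no defocus), texture inside cells, debris and plasma background structure,
cell deformation over time, and the full variability of real morphologies.
Passing the synthetic benchmarks therefore demonstrates that the machinery
is correct and well-calibrated on separable, ground-truthed input — not
that any particular accuracy transfers to microscope data; on real images
the ensemble members are expected to be replaced or retrained through the
curation loop (`export_for_curation()` → expert edit → `merge_curated()` →
retrain), which is the documented adaptation path for new imaging
conditions.

# Problem sizes used by the test-suite and acceptance script

The package's own benchmark conditions, chosen once: classifier benchmark
500 crops/class with a stratified 90/10 split, repeated over 5 seeds;
whole-frame classification benchmark 6 scenes of 25 cells (about 150 cells)
against rendered ground truth; imbalance benchmark one oversampling member
trained on class counts 500 down to 100 and scored on a balanced fresh set;
segmentation counting benchmark 50 scenes of 10–50 non-overlapping cells at
640 × 640 px; tracker benchmark 10 well-confined cells (5 × 2 grid on a
1280 × 1024 frame, drift ≤ 0.3 px/frame, jitter SD 2 px) over 200 frames;
effect-size parameter recovery from 5,000 normal draws per class; bootstrap
coverage from 500 simulations of n = 1000 with B = 1000 replicates inside
each simulation (B = 10,000 stays the user-facing default; BC coverage is
insensitive to B at this scale and the simulation count is what controls
the Monte-Carlo error of the coverage estimate).

# Known limitations

* The pixel-classifier default is a deliberately small logistic model; it
  is the contract's reference implementation, not a state-of-the-art
  segmenter.
* Tracking is purely motion-based (distance cost only); there is no
  appearance model, so two cells that swap positions within one frame
  interval are indistinguishable. Well confinement makes this rare in the
  intended setting.
* The median statistic quantises intensities to 256 levels; images with
  meaningful sub-level contrast should use the mean or Gaussian statistic.
* Histogram binning (4–10 µm at 0.1 µm), the Bonferroni multiplicity, the
  reliability bin count and the cleaning fences are all conventions exposed
  as parameters; published analyses rarely state them, so results should
  quote the values used.
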