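---
title: "Methods: image-based epigenetic profiling of nuclear marker puncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based epigenetic profiling of nuclear marker puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Super-resolution fluorescence microscopy of cell nuclei stained for an
active-chromatin histone mark (H3K27ac), an architectural protein (CTCF) and
DNA resolves discrete nuclear *puncta* — bright foci a few hundred
nanometres across that plausibly correspond to active regulatory regions
(H3K27ac) and chromatin anchors (CTCF). Perturbations that remodel the
epigenome (e.g. HDAC inhibition by valproic acid, or MECP2 mutation in Rett
syndrome models) change the abundance, brightness, shape, radial placement
and mutual proximity of these puncta. `nucleoprofiler` quantifies those
changes per nucleus, classifies epigenetic states with a small residual CNN,
and interprets the classifier with Score-CAM heatmaps that are themselves
quantified with radial nuclear metrics.

All coordinates in the package are 1-based (row, col) pixel centres with
inclusive bounding boxes — the R raster convention. Angles are measured from
the positive column axis towards the positive row axis, normalized to
[0, pi).

# The synthetic-data generator

Real super-resolution data is large and external; every stage of the
package is instead exercised on synthetic single-nucleus images whose
ground truth is known exactly.

A simulated nucleus is an ellipse with semi-axes drawn uniformly from
configured ranges (default 180–230 by 120–170 px on a 600-px canvas at
50 nm/px, matching the scale of deconvolved spinning-disk data), orientation
uniform in [0, pi) so that heatmap alignment is genuinely exercised. The
DNA channel is the filled ellipse smoothed with a 2-px Gaussian edge. Each
marker channel is a constant background (default 100) plus isotropic 2D
Gaussian foci — sigma = radius/2, i.e. PSF-convolved spots rather than hard
discs, so multi-Otsu sees realistic intensity structure — plus additive
Gaussian noise (default sd 10). Punctum counts are Poisson (negative
binomial optional), radii uniform in 2–5 px, peaks uniform in 500–1500
image units: a deliberately heterogeneous population, since real foci vary
severalfold in brightness.

Radial placement: a punctum first draws one of five concentric elliptical
zones with probability `zone_weights`, then a position uniform *by area*
within that zone. Inter-channel colocalization: a fraction `rho` of
channel-2 puncta is placed at channel-1 positions with optional Gaussian
jitter. An optional second population (`extra_foci`) confined to one
quadrant of the ellipse frame supports localization experiments. A
`min_separation` option rejection-samples positions at a minimum mutual
distance where an experiment's design requires resolvable foci.

Everything is a pure function of (configuration, seed).

What the generator does *not* emulate: nucleoplasm texture, nucleoli,
photophysics (blinking, bleaching), anisotropic PSFs, 3D structure, and
spatially correlated noise. Passing tests therefore demonstrate
correctness of the measurement pipeline under controlled conditions, not
performance on real micrographs.

# Nucleus segmentation and quality control

The package substitutes a classical segmenter for learned instance
segmentation: Otsu threshold on a lightly smoothed DNA channel, hole
filling, Euclidean distance transform, watershed on the inverted distance
map to split touching nuclei. A contrast guard (foreground mean must exceed
the background mean by 3 background-sds) prevents Otsu from hallucinating
foreground on blank fields.

QC rejects a segmented nucleus when any of: box aspect-ratio z-score > 1.5
(z over the processing batch, sample sd, defined as 0 for batches under 2),
any bounding-box side outside 200–600 px, roundness < 0.7, or the pixel
area fails the area rule. Roundness is defined here as circularity
4&#960;A/P&#178;, with the perimeter measured as the subpixel 0.5-level
contour of the lightly smoothed mask — accurate to ~1–2% on both smooth
discs and polygons, where chain-code estimators err several percent on one
or the other (thin shapes fall back to the raw contour). The area
rule defaults to rejecting area *below* 30,000 px&#178;: a rejection rule
"area > 30,000" would contradict the side-length rule, since a round
nucleus at the minimum accepted side (200 px) already has area
~31,400 px&#178;; the opposite direction remains available via
`qc_thresholds(area_rule_direction = "greater")`. Accepted crops are
zero-padded, centred, onto a 600-px canvas.

# Puncta segmentation

Within the nucleus mask, intensities are split into four classes by
multilevel Otsu (exhaustive between-class-variance maximization on a
128-bin histogram; computed on mask pixels only so the zero-padding class
cannot contaminate the levels). The brightest class is the punctum
foreground (top two classes optional). The Euclidean distance transform of
the foreground is segmented by watershed on its inversion; local maxima are
merged within a height tolerance of 1 and a 3-px neighbourhood, which
splits dumbbells of touching foci while never oversplitting an isolated
convex spot. Objects larger than 300 px&#178; are removed (strictly
greater: exactly 300 is kept). Each remaining punctum is measured: area,
centroid, mean intensity from the original image, and major/minor axis
lengths of the moment-equivalent ellipse; the effective radius is
(L_major + L_minor)/4.

Per-nucleus features: punctum count N; mean area; mean intensity; mean
elongation (irregularity), excluding single-pixel puncta whose minor axis
is zero (their count is reported separately); and per-zone densities
n_j · 250 / A_j — puncta per 250-px&#178; unit of zone area, with zone
membership decided by the centroid. With N = 0 the count is kept and the
means are recorded as missing, never as zero.

# Concentric zones

The fitted nucleus ellipse (image-moment fit of the mask's largest
component) is divided into five concentric zones bounded by scaled copies
of the ellipse at fractions j/5 of the semi-axes — zone 1 the centre, zone
5 the nuclear periphery. Scaled-copy boundaries (rather than equal-area
rings) are the natural reading of "concentric elliptical zones based on
the fitted ellipse"; densities are area-normalized anyway, and the zone
count is an internal parameter fixed at 5 in the public API. A pixel at
normalized elliptical radius exactly j/5 belongs to zone j (upper bound
inclusive); the five zones partition the ellipse interior exactly.

# Colocalization

Directional mean minimum centroid distance (for each source punctum, the
distance to its nearest target punctum; histogrammed in left-closed 10-px
bins) and the overlap ratio: the fraction of source puncta with at least
one target punctum at centroid distance d &#8804; r_i + r_j. Both
directions are reported separately; no symmetrization. Distances stay in
pixels; physical conversion via the pixel pitch is never applied silently.
Cells with an empty puncta set yield missing values that are excluded from
group statistics.

# The classifier

The default architecture (`9conv_1f`) is a nine-convolution residual
network: a 7×7 stride-2 stem (the kernel spans ~350 nm at 50 nm/px, large
enough to cover a resolvable structure plus context), then four residual
blocks of two 3×3 convolutions, batch normalization after every
convolution, ReLU activations, and one fully connected layer producing a
single sigmoid logit trained with binary cross-entropy. Shortcuts are
parameter-free — identity where shapes match, stride-2 subsampling with
zero-padded channels at stage transitions — keeping the convolution census
at exactly nine; the exact shortcut placement is the package's choice of a
standard 4-block layout. Variants add global average pooling
(`9conv_gap_1f`) or double the block count (`17conv_gap_1f`). Single-channel
images are duplicated across three planes (pseudo-RGB), so the same
architecture serves single- and three-channel experiments.

Training follows the reference regimen — Adam, initial learning rate 1e-4
decayed to 1e-6, batch 128, 300 epochs, stratified 80:20 split — with every
value scalable through `train_config`. The decay shape is cosine (the
regimen states only "decayed"). No pretrained weights ship with the
package: initialization is He-normal under a fixed seed, and a user hook
can load externally trained parameters. Desk-scale experiments in the
test-suite and acceptance script use 128-px inputs, width 4, batch 32,
20 epochs and learning rate 1e-3 → 1e-5: a random-initialized small network
needs a larger step size than a fine-tuned pretrained one, and 400-image
problem sizes keep a full training run around a minute on one CPU. The
convolution forward/backward passes are im2col + GEMM kernels in
RcppArmadillo; everything else (batch norm, Adam, scheduling) is plain R.

# Score-CAM

For a chosen layer (default: the last convolutional block), each of the K
activation maps is bilinearly upsampled to input size, min–max normalized
to [0, 1] (constant maps are skipped with a warning), multiplied
elementwise with the input, and forward-passed; the target-class scores of
these masked inputs, softmaxed over K, weight the normalized maps, and a
final ReLU gives the per-pixel score S(p) ≥ 0. The weighted sum is *not*
renormalized to [0, 1]: the two nuclear metrics are mean- and ratio-based,
and preserving the output scale keeps cells from the same model
comparable.

Two metrics summarize a heatmap against its nucleus mask. Nuclear
intensity is the mean of S over M, the mask pixels with S > 0; with no
such pixels the metric is missing, never 0. Nuclear periphery enrichment
divides the mean of S over *all* pixels of zone 5 (zeros included) by the
nuclear intensity (zeros excluded) — the two means deliberately treat
zeros differently, following the two definitions verbatim; a uniform
heatmap scores exactly 1. Nuclear intensity is scale-equivariant and
periphery enrichment scale-invariant.

For group-average visualization only, heatmaps are rotated by the negative
nucleus orientation and anisotropically scaled so the fitted semi-axes map
onto canonical axes (default 150 × 100 px), resampled bilinearly (masks:
nearest) and averaged pixel-wise; per-cell metrics always use the original
coordinate space.

A frozen, versioned battery of standard region features (version
`r nucleoprofiler::cam_battery_version`) spans five categories — Size,
Shape, Intensity, Edge (Sobel-gradient based; the edge-pixel count uses a
half-maximum gradient threshold so a constant map has zero edges), and
Texture (histogram entropy plus a Haralick subset via EBImage) — at four
or more features per category. Full parity with ~90-feature reference
batteries is out of scope; the battery is frozen so per-category fractions
of significant features are reproducible within the package.

# Low-resolution simulation

Conventional-resolution imaging is simulated by convolving each channel
with a normalized 11×11 Gaussian kernel whose sigma follows the frozen
automatic convention sigma = 0.3·((k−1)/2 − 1) + 0.8 (2.0 px at k = 11),
with reflect-101 borders. At 50 nm/px the kernel spans 550 nm, more than
four times the ~120 nm effective super-resolution limit, so submicron
puncta merge as they would under a conventional microscope. The
degradation experiments use a deliberately dense fixture (~300 foci of
radius ≤ 2 px at ≥ 3 px separation per nucleus): blur collapses
neighbouring foci into joint blobs, so the segmented count and the
per-punctum detection rate both drop — the mechanism behind
resolution-dependent feature loss.

# Group statistics

Per-feature comparisons between two conditions use the independent
two-sample Student's t-test with pooled variance (Welch optional),
two-sided, dropping missing values per feature and skipping features with
fewer than two usable values in a group. Per-category summaries report the
fraction of features with raw p < 1e-2; no multiple-testing correction is
applied by default, matching the raw-p screening convention (a
Benjamini–Hochberg option exists). Box-plot IQR trimming (fences Q1 −
1.5·IQR, Q3 + 1.5·IQR, type-7 quantiles, single pass) exists strictly for
visualization: `compare_features` has no trimming parameter by
construction.

Degenerate inputs are handled explicitly: identical groups give t = 0,
p = 1; two groups with zero within-group variance but different means are
reported as a 0-limit p with a warning.

# Problem sizes and numerical choices

Test-suite and acceptance problem sizes are the package's own desk-scale
choices: 20 nuclei × ~50 puncta for recovery (detection ≥ 95%, centroid
RMSE ≤ 1.5 px measured against ground truth with a 3-px one-to-one match
radius); 100 random configurations for exact brute-force agreement of the
colocalization metrics; 400-image two-class sets at 128 px for
classification; 50 held-out images for Score-CAM localization; 100
features × 50 cells/group × 20 repetitions for type-I calibration of the
significance screen.

Numerical conventions frozen in code: multilevel Otsu on 128 histogram
bins; watershed tolerance 1 / neighbourhood 3 px for puncta (10 / 7 px for
nuclei); He initialization; batch-norm epsilon 1e-5, momentum 0.1; bilinear
interpolation for heatmap resampling with zero outside the source; the
sigma convention above for blurring. The puncta-recovery fixture narrows
the punctum peak range to 800–1200 because the method's foreground is
defined as the single brightest Otsu class: a population spanning a 3×
intensity range straddles Otsu classes by construction, which measures
intensity heterogeneity rather than spatial recovery.

# Known limitations

- The classical nucleus segmenter handles touching, roughly convex nuclei;
  heavily overlapping or irregular nuclei need a learned segmenter.
- Puncta metrics are 2D; axial structure is invisible.
- The classifier's reported numbers on synthetic data say nothing about
  accuracy on real micrographs; the synthetic generator's simplifications
  (above) bound what the tests demonstrate.
- Score-CAM heatmaps inherit the resolution of the target layer (8×8 at
  128-px input before upsampling); fine-grained attributions require an
  earlier layer.
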