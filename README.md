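# nucleoprofiler

Quantitative, interpretable analysis of multi-channel super-resolution
images of cell nuclei stained for an active-chromatin histone mark
(H3K27ac), the architectural protein CTCF, and DNA. The package is aimed at
imaging groups who want per-nucleus, per-punctum measurements of chromatin
organization — and a classifier whose decisions can be mapped back onto the
nucleus — without shipping terabytes of raw data: every stage is testable
against a built-in synthetic-nucleus simulator with exact ground truth.

## What it computes

**Nuclear puncta.** Bright foci in a marker channel are segmented by
four-class multilevel Otsu thresholding (brightest class = foreground)
followed by marker-based watershed on the inverted Euclidean distance map,
discarding objects above 300 px². Per nucleus: punctum count *N*, mean area
(1/N)ΣAᵢ, mean intensity (1/N)ΣIᵢ, irregularity (1/N)Σ Lᵢᵐᵃʲ/Lᵢᵐⁱⁿ, and
radial densities d_j = n_j·250/A_j over five concentric elliptical zones
(part1 = centre … part5 = periphery) of the moment-fitted nucleus ellipse.

**Colocalization.** Directional mean minimum centroid distances between the
two marker channels, and the overlap ratio: the fraction of source puncta
with at least one target punctum at centroid distance d ≤ rᵢ + rⱼ, where
r = (Lᵐᵃʲ + Lᵐⁱⁿ)/4 is the effective radius.

**Classification + interpretation.** A nine-convolution residual CNN
(7×7 stem, four residual blocks, batch norm after every convolution, one
fully connected sigmoid logit; pseudo-RGB duplication for single-channel
input) classifies two epigenetic states. Score-CAM heatmaps S(p) are
quantified by Nuclear Intensity = (1/|M|)Σ_{p∈M} S(p) over nonzero mask
pixels M, and Nuclear Periphery Enrichment = mean over all part5 pixels
divided by Nuclear Intensity, plus a frozen five-category standard feature
battery.

**Resolution studies.** Conventional microscopy is simulated by an 11×11
Gaussian blur (σ = 2.0 px by the automatic convention; 550 nm footprint at
50 nm/px, >4× the ~120 nm super-resolution limit).

**Group statistics.** Per-feature independent two-sample t-tests,
per-category fractions of features with p < 1e-2, and box-plot IQR
trimming for visualization only.

## Worked example

```r
library(nucleoprofiler)

cfg <- synth_config(puncta_count_mean = 50, coloc_fraction = 0.3,
                    puncta_peak = c(800, 1200), min_separation = 8)
x  <- generate_nucleus(cfg, seed = 7)

h3 <- segment_puncta(x$image$channels$H3K27ac, x$image$mask)
ct <- segment_puncta(x$image$channels$CTCF,    x$image$mask)
h3
#> puncta_set: 39 puncta

puncta_aggregates(h3)
#> N = 39, mean area = 11.3 px^2, mean intensity = 909, irregularity = 1.18

part <- partition_zones(fit_ellipse(x$image$mask), dim(x$image$mask))
round(zone_densities(h3, part)$density, 3)
#> [1] 0.309 0.145 0.074 0.089 0.076

min_distances(h3, ct)$mean_min_distance
#> [1] 11.33
overlap_ratio(h3, ct)
#> [1] 0.436
```

Reading the numbers: the generator planted ~50 foci (Poisson; 39 realized
in this nucleus's H3K27ac channel) of 2–5 px radius. Mean punctum area
11.3 px² and irregularity 1.18 say the segmented foci are small and nearly
round. Zone densities *decline* outward even though every zone received the
same expected punctum count, because outer annuli are larger — density is
per 250-px² of zone area. With 30% of CTCF foci planted on H3K27ac
positions, 43.6% of H3K27ac puncta overlap a CTCF punctum under the
effective-radius rule, and the mean nearest-CTCF distance is ~11 px
(~0.57 µm at 50 nm/px).

The full pipeline (field simulation → nucleus segmentation → QC → padding →
puncta → colocalization → tidy feature CSV) is one call:

```r
res <- run_pipeline(run_config(n_nuclei = 12, seed = 1, out_dir = "out"))
head(res$features)
```

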