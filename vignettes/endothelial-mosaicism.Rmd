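---
title: "Quantifying endothelial-cell mosaicism in confocal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endothelial-cell mosaicism in confocal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

En-face ("whole mount") confocal images of large-vessel endothelium show
strikingly non-uniform protein distributions: punctate phosphatase staining
(VE-PTP) concentrated in the downstream half of cells, patchy per-cell
mosaics of activated receptor (Tie2-pY992) and tight-junction protein
(claudin-5), and irregular patches of extravasated IgG marking historical
plasma leakage. `endomosaic` turns such multichannel 8-bit images into a
reproducible set of numbers: particle counts by size class, downstream
polarization percentages, colocalization fractions and cross-correlation
shift curves, membrane/cytoplasm compartment fractions, heterogeneity
statistics, circumferential band profiles, and marker-stratified leakage
densities.

Because no public micrographs accompany the protocol this package
implements, it ships a synthetic endothelial-sheet generator whose ground
truth is exact. Every analysis stage is validated by recovering known
generator parameters, not by eyeballing real images.

## Conventions and calibration

All rasters are row-major with the origin at the top-left. The blood-flow
axis runs along image columns, increasing downstream (flow left to right);
"upstream/downstream" always resolves to column comparisons. The standard
calibrations are 0.124 µm/px (x100), 0.132 µm/px (x63) and 0.311 µm/px
(x40) on 1024 x 1024 frames; `image_area_mm2()` computes the field area as
`width * height * pixel_size^2 * 1e-6` at full precision (a 1024² frame at
0.124 µm/px is 0.0161 mm² to three significant figures). Display rounding
(three significant figures for areas, one decimal for diameters) is
presentation-only. Note the x63 computation (0.01827 mm²) and commonly
quoted 0.0182 differ in the third significant figure; this package always
computes from the formula rather than storing printed areas.

## Particle detection and size classes

Masks come from a strict `>` threshold ("above an intensity threshold"),
default 60 on the 0-255 scale (100 for the permeabilization comparison).
Particles are 8-connected components — the common particle-analysis
convention — while cells are 4-connected components of the junction-mask
complement, so single-pixel diagonal junction lines still separate
neighbouring cells. Components are binned by pixel count: small (1-10 px),
medium (11-100 px), large (> 100 px), with the large class optionally split
at 200 px for compartment analysis. Equivalent circular diameters
(`2 * sqrt(n * p² / pi)`) map the bin edges to ~0.4 µm and ~1.4 µm at
0.124 µm/px.

## Cells, sampling and the polarization statistic

`segment_cells()` labels the complement of the junction mask, discards
components below `min_area` (default 200 px ≈ 3 µm², suppressing speckle
and junction holes) and flags border-touching components. Each cell splits
into halves at its area-centroid column — robust for curved elongated
cells, unlike a bounding-box midpoint. Particles attach to cells by their
centroid pixel; a centroid exactly on the split column counts as downstream
(a deterministic tie-break).

For per-cell statistics, `sample_cells()` emulates choosing "uniformly
distributed" cells: a 2 x 4 tile grid for the default k = 8, each tile
taking the nearest eligible (non-border) unchosen centroid, preferring
centroids inside the tile. The rule is deterministic; the `seed` argument
exists only for interface symmetry. Polarization pools upstream/downstream
counts across the sampled cells *before* forming the percentage, so sparse
classes never produce undefined per-cell ratios; an empty class is reported
missing, never zero.

## Colocalization and the cross-correlation shift

`coloc_fraction()` reports exact binary overlaps in both directions (the
two are asymmetric whenever one structure is a focal subset of the other).
`van_steensel_ccf()` computes the Pearson correlation of two intensity
channels at every integer shift in [-S, +S] along the flow axis (S = 20 by
default, i.e. 41 values; descriptions of this procedure sometimes quote "40
values" for the same range, an off-by-one we resolve in favour of the full
symmetric range). Correlations use raw intensities over the overlapping
columns only — no zero padding — so edge columns never dilute the
correlation. With `ccf(d) = cor(A[, j], B[, j + d])`, a positive peak means
the structure in the reference channel B lies downstream of the structure
in A; equivalently, non-colocalized A-signal sits upstream of the
colocalized signal. Ties at the peak break toward shift 0. The peak shift
converts to micrometres via the calibration (e.g. a mean of +5.3 px at
0.124 µm/px is 0.66 µm).

## Compartment assignment by permeabilization

Membrane versus cytoplasm residency is inferred by comparing a
permeabilized specimen (all particles stained) with a non-permeabilized one
(membrane particles only), both thresholded at 100 and binned with the
four-level size classes. The membrane fraction per bin is
`100 * nonperm / perm` on per-image aggregate counts — the two images are
different specimens, so no particle matching is attempted. Fractions can
exceed 100% under sampling noise; they are reported as-is and flagged.

## Heterogeneity statistics

`heterogeneity()` reports mean, SEM and the coefficient of variation
(sample SD, n-1 denominator, divided by the mean, as percent) — the
heterogeneity index used throughout. `ols_fit()` wraps `stats::lm()` for
simple regression with R² and the two-sided slope p-value;
`ks_two_sample()` wraps `stats::ks.test()` with the asymptotic p-value
(exact small-sample p-values are out of scope). `band_profile()` tiles a
circumference panorama into sequential non-overlapping bands (default
1500 x 250 px; any remainder shorter than one band is dropped) and reports
per-band thresholded area densities; band geometry is fully configurable
because published descriptions of the region size and orientation vary.
`normalize_to_mean()` rescales a profile to mean 1 before cross-channel
comparisons.

## Leakage stratification

`igg_density()` is the thresholded tracer area density within an ROI.
`density_by_marker()` splits the ROI into marker-positive and
marker-negative strata using the raw marker mask (no dilation by default; a
dilation radius is available for sensitivity analysis) and satisfies the
exact identity `overall = (|M| d_M + |M̄| d_M̄) / |ROI|`.
`marker_leakage_regressions()` fits the three standard comparisons across
images (each stratum vs total, stratum vs stratum).

## The synthetic sheet generator

`generate_mosaic()` builds the cell map from a jittered grid of exactly
`n_cells` seed points assigned by nearest-seed distance under an
anisotropic metric (columns compressed by the elongation factor, so cells
stretch along the flow axis). Vessel presets fix elongation at 3.0
(aorta-like) and 1.2 (vena-cava-like). Label boundaries become junction
lines (2 px wide by default, intensity 150), over background 20 with
additive Gaussian noise (sd 6) clipped to [0, 255]. Tessellated cells were
chosen over textured micrograph mimicry because the ground truth must be
exact; realism is secondary to testability.

`render_particles()` draws, per cell: Poisson(15) small disks placed
uniformly; Poisson(6) medium disks whose cell half is a Bernoulli draw with
downstream probability `q_medium` (default 0.8); and with per-cell
probability `pi_large` (0.54 aorta-like, 0.88 vena-cava-like) one large
disk anchored at the most-downstream interior pixel of the cell, partially
overlapping the junction line — the "downstream tip" geometry. Disk radii
come from discrete sets whose rasterized areas fall inside the intended
bins (1/5/9 px for small, 13-81 px for medium, 113-253 px for large,
spanning both large sub-bins). Particle intensity is 180, above every
analysis threshold even at 100.

Numerical details that matter for correctness:

* All centres are drawn from the cell *core* (≥ 2 px from neighbouring
  cells), so every particle unambiguously belongs to one cell under
  centroid assignment, and disks stay clear of the image border so
  rasterized pixel counts are exact.
* Disks never touch: placement rejects collisions (50 uniform retries, then
  an exact free-set draw within the requested region). Only when the
  requested region is truly packed is an overlapping placement forced,
  inside that region — so half assignments always honour `q_medium` — and
  counted in the manifest (`n_forced`, `collision`). At the default
  densities no forced placements occur.
* The hard-disk interaction has one visible consequence: with tips and
  mediums concentrated downstream, accepted positions of uniformly-proposed
  small particles end up mildly upstream-shifted (~40% downstream under the
  default asymmetric model). Under a symmetric model (q = 0.5, no tips)
  smalls measure 50% as expected. Real endosome distributions are not
  hard disks; this is a limitation of the generator, not of the analysis.

`render_marker_mosaic()` marks a target fraction of cells positive by
seeded cluster growth on the cell adjacency graph (contiguity parameter;
0 reproduces independent assignment), staining either cytoplasm or a
junction-localized halo. `render_igg()` thresholds a Gaussian-smoothed
random field at the quantile matching the target area fraction — the
realized fraction is exact to ~1 pixel in 10⁴ — optionally anti-correlated
with a marker mask. `render_ccf_phantom()` translates a base channel by a
known column offset with optional noise. `simulate_permeabilization_pair()`
renders two independent sheets sharing one particle model; the
non-permeabilized render draws only membrane-resident particles
(per-bin membrane probabilities 0.36/0.27/0.37/0.90).

Everything is seeded: `(spec, model, seed)` determines all channels and
manifests bit-for-bit.

What the generator does *not* emulate: point-spread blur, uneven
illumination, staining gradients, cell-shape irregularity beyond jittered
tessellation, 3-D curvature, and intensity-correlated noise. Passing the
recovery suites therefore demonstrates that the analysis chain is unbiased
and correctly calibrated on images whose statistical structure matches its
assumptions — not that thresholds of 60/100 are optimal for any particular
microscope.

## Validation strategy and problem sizes

The test suite validates against independent oracles: connected components
against a brute-force flood fill on all 512 3 x 3 patterns (both
connectivities), OLS against explicit normal equations to 10 digits, the KS
statistic against exhaustive ECDF enumeration for all samples of size ≤ 6
over a three-letter alphabet, and exact conservation identities (particle
pixels vs mask pixels; cell areas + junction + discarded = image area;
leakage stratification identity).

Statistical recovery runs on 200-cell 768 x 768 sheets (vena-cava-like
geometry): medium-particle polarization at q ∈ {0.5, 0.8, 0.97} within 99%
binomial intervals of the pooled particle count; the per-cell
large-particle probability 0.88 within its binomial interval over pooled
cells; cross-correlation offsets -10..+10 recovered exactly without noise
and within ±1 px at SNR 5; IgG patch fractions 0.31 and 0.92 within 2
points. The compartment suite pools independent permeabilization pairs at
`pi_large = 1` — membrane fractions are per-particle Bernoulli splits, so
raising the large-particle rate adds power in the sparse > 200 px bin
without changing the estimand. These sizes keep the full suite around a
minute and a half on one CPU while leaving the binomial bands meaningfully
tight.

## Known limitations

* Per-cell assignment is centroid-based; a particle straddling a junction
  is attributed to the cell under its centroid, or to none.
* Cells are segmented only from junction staining; broken junction lines
  merge cells (no gap inpainting beyond the `min_area` hole suppression).
* The asymptotic KS p-value is inaccurate for very small samples.
* The CCF searches shifts along the flow axis only, matching the
  upstream/downstream question; it is not a 2-D registration.
* Group comparisons across biological replicates (t-tests, ANOVA) are left
  to standard tools; the package supplies the per-image measurements.
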