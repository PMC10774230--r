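# endomosaic

Quantification of endothelial-cell mosaicism in en-face confocal images of
vascular endothelium.

Large-vessel endothelium is far from uniform: punctate phosphatase staining
(VE-PTP) concentrates in the downstream half of cells under flow, activated
receptor (Tie2-pY992) and tight-junction protein (claudin-5) form patchy
per-cell mosaics, and extravasated IgG marks irregular regions of historical
plasma leakage. `endomosaic` is an R package for turning multichannel 8-bit
confocal images of such endothelial sheets into reproducible measurements,
for vascular biologists and image analysts who need the full pipeline —
segmentation through statistics — scripted and testable rather than clicked
together interactively.

## What it computes

With the flow axis along image columns (downstream = increasing column):

* **Particles** — strict-threshold binary masks (default threshold 60 of
  0–255), 8-connected components, three size classes by pixel count
  (1–10, 11–100, > 100 px; equivalent circular diameters
  `d = 2·sqrt(n·p²/π)` ≈ 0.4 and 1.4 µm at 0.124 µm/px), counts per cell
  and area densities.
* **Cells** — 4-connected components of the junction-mask complement, each
  split into upstream/downstream halves at its area-centroid column;
  spatially stratified sampling of k = 8 cells.
* **Polarization** — per size class, the percentage of particles in the
  downstream half, pooled over sampled cells; the fraction of cells
  carrying a large (> 100 px) particle.
* **Colocalization** — exact binary overlap fractions in both directions,
  and van Steensel cross-correlation curves: Pearson correlation at every
  integer shift in −20..+20 px along the flow axis, peak shift in px and µm.
* **Compartments** — membrane fractions per size bin (large class split at
  200 px) from permeabilized vs non-permeabilized specimen pairs at
  threshold 100.
* **Statistics** — coefficient of variation (sample SD / mean), simple
  regression with R² and slope p-value, two-sample Kolmogorov–Smirnov,
  circumferential band profiles (default 1500 × 250 px bands),
  normalization to the mean.
* **Leakage** — IgG area density, stratified by marker-positive vs
  marker-negative regions with an exact area-weighted identity, and the
  standard cross-image regressions.
* **Synthetic sheets** — a fully seeded generator (anisotropic cell
  tessellation, three particle classes with controllable downstream
  polarization and tip placement, marker mosaics, shifted CCF phantoms,
  patchy IgG fields, permeabilization pairs) with exact ground-truth
  manifests, used to validate every stage.

## Worked example

```r
library(endomosaic)

spec  <- sheet_spec(width = 512, height = 512, n_cells = 90,
                    vessel = "vena_cava")
sheet <- simulate_sheet(spec, particle_model(pi_large = 0.88), seed = 42,
                        igg_fraction = 0.31)
sheet$stack
#> <channel_stack> 512 x 512 px, 0.124 um/px, 3 channel(s): veptp, vecad, igg

cells <- segment_cells(binarize(sheet$stack$vecad, 60))
cells
#> <cell_map> 90 cell(s), 512 x 512 px

particles <- assign_particles(
  label_particles(binarize(sheet$stack$veptp, 60),
                  calibration = calibration(0.124)), cells)
classify_and_count(particles)
#>   size_class count
#> 1      small  1379
#> 2     medium   504
#> 3      large    87

polarization(particles, cells, sample_cells(cells, k = 8))
#>   size_class n_up n_down downstream_pct n_cells
#> 1      small   79     47       37.30159       8
#> 2     medium   10     41       80.39216       8
#> 3      large    0      8      100.00000       8

percent_cells_with_large(particles, cells)
#> [1] 96.66667

van_steensel_ccf(sheet$stack$veptp, sheet$stack$vecad,
                 calibration = calibration(0.124))
#> <ccf_curve> 41 shifts, peak +5 px (+0.62 um) ccf = 0.065

igg_density(binarize(sheet$stack$igg, 60))
#> [1] 31.00014
```

Reading the output: the generator placed medium particles downstream with
probability 0.8 and a large tip particle in 88% of cells; the pipeline
measures 80.4% medium polarization over the 8 sampled cells, 100% for the
large class (tips are downstream by construction), and a positive
cross-correlation peak — the junction signal sits a few pixels downstream
of the bulk particle signal, exactly the geometry of tip particles pressed
against the downstream junction. The IgG channel was drawn with a 31% patch
fraction and measures 31.0%. Small particles are placed uniformly, so their
measured 37% reflects sampling scatter plus the hard-disk interaction
discussed in the vignette.

Real images enter the same way via
`load_stack("img.tif", c(veptp = 1, vecad = 2), calibration(0.124))`, and
`run_pipeline()` batches any number of stacks into a tidy
(image, metric, channel, value) table under a serializable `run_config()`.

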