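# centriomorph

Nanoscale centriole morphometry for ultrastructure expansion microscopy
(U-ExM), with a built-in synthetic image generator for validation by
parameter recovery.

Centrioles are barrel-shaped organelles built from nine microtubule
triplets, lined over their central core by a helical inner scaffold.
U-ExM physically expands specimens ~4.2× in a swellable gel, so that
ordinary confocal imaging resolves where individual proteins sit relative
to the microtubule wall. Turning such images into numbers requires a
small zoo of measurements, which this package implements as a tested,
reusable pipeline for cell biologists quantifying centriole architecture:

- **Calibration** — gel expansion factor `X = gel size / 12 mm`;
  all outputs are biological nm (expanded distances divided by `X`).
- **Radial mapping** (top views) — per-triplet offset
  `Δ = r_tubulin − r_protein` between the wall intensity peak and the
  protein peak along radial spokes, positive toward the lumen
  (inner-scaffold proteins sit at Δ ≈ 15–28 nm, wall proteins at ≈ 0).
- **Longitudinal metrics** (lateral views) — tubulin and protein signal
  lengths by half-maximum crossings, coverage
  `% = 100 · L_protein / L_tubulin`, band positioning, and wall-to-wall
  diameter in the proximal / core / distal regions.
- **Shape & integrity** (top views) — roundness as the minor/major ratio
  of a least-squares ellipse fit to the wall peaks (polygon circularity
  `4πA/P²` alongside), and broken-wall detection from the largest angular
  gap in the wall trace.
- **Confocal quantification** — focus detection and per-cell dot
  counting, fixed-area centrosomal intensity, 25-point centriolar line
  profiles, and normalization to the control mean (A.U.).
- **Periodicity** — dominant repeat of decorated-microtubule line
  profiles by detrended autocorrelation (periodogram cross-check),
  e.g. the ~8.5 nm decoration repeat on in vitro microtubules.
- **Statistics** — Mann–Whitney (exact for small samples), one-way ANOVA
  with Holm–Šidák step-down comparisons, Fisher's exact test, unpaired t,
  star annotations, and a per-condition report builder.

Because every estimator is validated against the bundled generator
(`simulate_centrioles()`, `generate_cell_field()`,
`generate_decoration_profile()` plus ground-truth manifests), the package
needs no external data to demonstrate correctness: rendered offsets,
lengths, coverages, ellipticities, fractures and repeats are recovered
within stated tolerances. See the vignette
(`vignettes/centriole-morphometry.Rmd`) for the underlying models and
design choices.

## Worked example

Simulate five top-view centrioles of the human control condition (POC5
channel, an inner-scaffold protein placed 27 nm inside the wall), then
measure the radial offsets back:

```r
library(centriomorph)

calib <- expansion_calibration(gel_size_mm = 50.4)
calib
#> Expansion calibration: gel 50.4 mm / coverslip 12.0 mm -> X = 4.20
#>   pixel 35 nm, z-step 120 nm (expanded space)

sim <- simulate_centrioles("hs-control", n = 5, view = "top",
                           channel = "POC5", seed = 7)
img <- sim$images[[1]]
img
#> centriole_image (top view): 45 x 45 px, channels: tubulin, protein

ctr <- find_center(img)
measure_triplet_offsets(extract_spokes(img, ctr))
#> Radial offsets: mean 26.9 nm +/- 2.9 (n = 9 resolved)

all <- lapply(sim$images, function(im)
  measure_triplet_offsets(extract_spokes(im, find_center(im))))
aggregate_offsets(all, rep("control", 5))
#>     group mean_delta_nm sd_delta_nm  n
#> 1 control      27.36799    2.634401 45
```

The pooled mean of 27.4 nm over 45 spoke measurements recovers the 27 nm
shell offset encoded in the preset; the ~2.6 nm scatter is measurement
noise at the default imaging settings. The same pattern applies to
lateral views (`axial_profile()` → `measure_length()` →
`coverage_and_position()` → `measure_diameter()`), top-view shape
(`detect_wall_peaks()` / `wall_ridge_points()` → `compute_roundness()`,
`assess_wall_integrity()`), cell fields (`detect_foci()` →
`count_dots_per_cell()`, `centrosomal_intensity()` →
`normalize_to_control()`) and 1-D profiles (`estimate_period()`).
Condition presets (`cr-wildtype`, `hs-control`, `hs-siwdr90`,
`wdr90-decoration`) live as YAML under `inst/extdata/presets/`.

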