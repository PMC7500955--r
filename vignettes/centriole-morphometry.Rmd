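---
title: "Nanoscale centriole morphometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoscale centriole morphometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centriomorph)
```

## Scope

`centriomorph` quantifies centriole ultrastructure from ultrastructure
expansion microscopy (U-ExM) images: where a protein shell sits radially
relative to the microtubule wall, how far it extends along the centriole,
how round and intact the nine-fold wall is, and how strongly and in what
numbers centriolar proteins appear at confocal scale. Because study-grade
raw images are rarely shareable, the package treats a synthetic
expanded-centriole generator as a first-class module: every estimator in
the package is validated by parameter recovery against generated ground
truth, and the same generator documents, in executable form, exactly what
structural model each estimator assumes.

## Units and calibration

A gel expands the specimen by the expansion factor
$X = \mathrm{gel\ size\ (mm)} / \mathrm{coverslip\ size\ (12\ mm)}$,
typically around 4.2. Images are acquired at a fixed expanded-space pixel
size (default 35 nm in x, y; 120 nm z-steps). Every measurement in the
package is reported in *biological* nanometres: expanded-space distances
divided by $X$. Reported expansion factors are rounded half-up to two
decimals; computations keep full precision. (Published gel tables
occasionally truncate instead of rounding, so tests against recorded
tables use a one-unit-in-the-last-place tolerance.)

## The image model behind the generator

A top view renders the microtubule wall as a dense ring of Gaussian
sub-elements at the wall radius (default 110 nm biological, i.e. a 220 nm
wall-to-wall diameter — a configuration default, not a measured claim),
with a nine-fold amplitude modulation (depth 0.6) marking the triplets.
The protein channel is the same ring moved radially by the configured
offset, positive toward the lumen. A lateral view renders the two wall
lines of the barrel over a length drawn from a truncated normal
distribution, and a protein band covering a drawn fraction of that length.
Phenotypes are expressed geometrically: ellipticity as the minor/major
ratio of the ring cross-section, wall fracture as a removed angular arc,
depletion as a short band at the proximal end of the core.

Why a modulated ring rather than nine separate blobs? The estimators
operate on peak positions, which both renderings preserve; but a
continuous ring keeps the angular wall trace above the missing-sector
threshold between triplets, so that an intact centriole reads as intact
and a rendered fracture is measured at its rendered angular extent rather
than at the (larger) angle between surviving discrete blobs. This matches
how expanded centrioles actually look at ~140 nm PSF: triplets appear as
intensity maxima on a connected wall, not as isolated points.

The PSF is an isotropic Gaussian (default FWHM 140 nm in expanded space,
i.e. ~33 nm biological at $X = 4.2$). Because a Gaussian source blurred
by a Gaussian PSF is again Gaussian, the PSF is folded analytically into
the rendered primitives (Gaussian sub-elements; error-function edges for
the wall lines); images are therefore exact expectations, with no
discrete-convolution artefacts. Noise follows the usual counting model:
the expected image is scaled so its brightest pixel equals `photon_scale`
(default 200 counts), a constant background (default 5) is added, pixels
are Poisson-sampled, and Gaussian read noise (default SD 2) is added. The
defaults were chosen once so that per-spoke measurement scatter is of the
same order as published measurement SDs; acquisition photon statistics
are not published, so these are package conventions. With `noise = FALSE`
the generator returns the noise-free expectation, which the geometry
tests use.

Determinism: a batch seed drives per-image substreams
(`seed + 1009 * image_index`, reduced mod $2^{31}-1$), so identical
specifications and seeds reproduce images bit for bit, and the number of
broken centrioles in a batch is exactly `round(prevalence * n)`.

What the generator does **not** emulate: resolved A/B/C-tubules,
cartwheel and appendage substructure, 3-D tilt (views are ideal top or
lateral projections), depth-dependent or vectorial PSFs, and
expansion-anisotropy distortions. Recovery results therefore demonstrate
estimator correctness under the stated model, not robustness to every
real-world artefact.

## Radial mapping (top views)

The ring centre starts at the intensity centroid of the thresholded
tubulin channel and is refined by minimizing the angular variance of the
wall-peak radius — a centred ring has the same peak radius in every
direction, and the criterion stays meaningful for broken rings because
empty sectors are excluded. Spokes are then cast at the angular maxima of
the unrolled wall (the triplet positions), mirroring per-triplet manual
line scans; each spoke averages a small angular wedge (default 8°) and
samples radii every 0.5 px with bilinear interpolation.

Per spoke, the tubulin peak is the discrete maximum refined by a
three-point quadratic fit — subpixel accuracy without committing to a
peak model, which is adequate at 35 nm pixels. The protein peak is
searched within ±60 nm (biological) of the tubulin peak: wide enough for
the largest published shell offsets (~28 nm), narrow enough to exclude
the opposite wall (~220 nm away). A spoke is *unresolved* when either
peak rises less than 20 % of the channel's maximal spoke amplitude above
its local baseline, implementing the "resolved signal in both channels"
admission rule as a configurable prominence threshold. The offset is
$\Delta = r_{\mathrm{tubulin}} - r_{\mathrm{protein}}$, positive toward
the lumen, so published inner-scaffold offsets (0–28 nm) are positive.

A Gaussian PSF acting on a curved wall biases the radial peak slightly
inward (about 1 nm biological at the default radius and PSF; the bias
largely cancels in $\Delta$ because both channels curve alike, leaving
roughly 0.2 nm). This is documented rather than corrected: it is well
inside the ±3 nm recovery tolerance the package tests enforce, and a
correction would add model dependence to an otherwise assumption-light
estimator.

## Longitudinal metrics (lateral views)

The centriole axis is *not* taken from second-moment PCA: the two wall
lines inflate the transverse variance, and near the barrel length where
axial and transverse moments coincide the covariance eigenvectors rotate
freely, producing occasional grossly tilted axes. Instead the transverse
direction is found directly as the projection direction of maximal
bimodality (minimal intensity-weighted kurtosis — two sharp wall lines
are maximally platykurtic), by a 2° angular scan with local refinement;
the axis is its orthogonal. A round (top-view) mask has no kurtosis
contrast across angles and raises an ambiguous-axis error.

Signal lengths use the least arbitrary rule available given that manual
criteria are rarely stated: the extent between the outermost crossings of
half the background-subtracted maximum (threshold configurable), with
linear interpolation of the crossing positions. Background is estimated
from the profile tails. Coverage is
$100 \times L_{\mathrm{protein}} / L_{\mathrm{tubulin}}$ and positioning
is the band midpoint as a percent of the tubulin extent from the proximal
end; the proximal end is oriented by the protein-band rule (the inner
scaffold begins above the proximal region) unless a marker channel
dictates otherwise. Summaries round to integer nm and percent.

Diameters average a transverse profile over a 50 px band perpendicular to
the axis at the representative position of each region and report the
subpixel-refined distance between the two outermost wall peaks. Regions
follow two rules: in controls, proximal/core/distal are the intervals
below, within, and above the inner-scaffold band; in depleted cells,
proximal lies below the remaining belt, the core is scanned just above
the belt, and the distal region is the last 100 nm of the centriole.

## Shape and integrity (top views)

Roundness is the minor/major axis ratio of a direct least-squares ellipse
fit (the numerically stable Halir–Flusser solution) to wall points, with
the peak polygon's area, perimeter and circularity
($4\pi A / P^2$) reported alongside, so both the ellipse and the polygon
reading of "connecting tubulin peaks" are available. Two point sources
feed the fit: the nine triplet maxima from `detect_wall_peaks()`, and —
for strongly deformed centrioles whose triplet maxima merge under the PSF
near the minor axis — a dense per-sector wall ridge from
`wall_ridge_points()`, which keeps the fit well-posed down to axis ratios
of 0.5. A tilt proxy (radial SD over mean radius above 0.15) flags
oblique views whose apparent ellipticity is geometric, implementing the
"perfectly imaged top views" admission rule.

Wall integrity unrolls the wall into a 1°-sector max-over-radius trace;
sectors below 15 % of the trace maximum are missing, and the largest
contiguous missing arc defines the gap. The raw 0.15-crossing boundaries
of a PSF-blurred wall end sit well inside the true gap, so the gap
boundaries are refined to the half-maximum crossings of the trace —
unbiased edge localization for a blurred step — and a 60° rendered
fracture is measured at 60° rather than ~42°. The wall is *broken* when
the gap exceeds 45° (more than one missing triplet); the threshold is a
configuration default, since no published angular criterion exists, and
the continuous gap angle is always reported so users can classify
differently.

## Confocal foci and intensities

Foci are detected on a difference-of-Gaussians band-pass at the
diffraction scale, thresholded at 5 robust SDs above the filtered
background, with non-maximum suppression; counts are tabulated per
labelled cell region (segmentation is accepted as input, not performed).
Centrosomal intensity integrates a background-subtracted region of
exactly 20 pixels — read as a 20-pixel-*area* disc by default, with a
square-box alternative selectable because the published phrase is
ambiguous; the choice is part of the call signature and hence of the run
record. Centriolar intensity is the mean of a 25-point interpolated line
profile. Relative intensities (A.U.) divide every measurement by the
control-group mean, making the control mean exactly 1.

## Periodicity

Decoration repeats are estimated from the autocorrelation of the
detrended profile (moving-average window equal to the upper search
bound), with the dominant lag in the 6–12 nm search window — bracketing
both the 8 nm tubulin dimer repeat and the reported 8.5 nm decoration
repeat — refined quadratically. Autocorrelation was chosen as primary
because it is robust to non-sinusoidal bump shapes; a zero-padded
periodogram is the built-in cross-check. Significance compares the
autocorrelation peak to the scatter of autocorrelation values away from
the candidate repeat's harmonic and half-harmonic neighbourhoods, floored
at the white-noise level $2/\sqrt{n}$; the floor matters for nearly
noise-free periodic profiles, whose out-of-harmonic autocorrelation is
itself structured. A repeat is significant at a peak-to-noise ratio of 3.
The estimator reports an averaged, refined repeat rather than any single
spacing.

## Statistics

The reporting battery mirrors common practice in the field:
two-sided Mann–Whitney (exact by full enumeration of labelings when the
pooled sample is ≤ 12 — ties handled exactly — otherwise the
tie-corrected normal approximation), one-way ANOVA followed by
Holm–Šidák step-down pairwise comparisons
($\tilde p_{(i)} = \max_{j \le i} 1 - (1 - p_{(j)})^{m - j + 1}$, capped
at 1) on the pooled residual variance, two-sided Fisher's exact test, and
the unpaired t test (pooled variance, Welch selectable). Stars follow the
usual convention (\*p<0.05 through \*\*\*\*p<0.0001); SDs are sample SDs.
An automatic normality gate for choosing t versus Mann–Whitney is
deliberately *not* enabled by default: silent test switching harms
reproducibility, so the chosen test is an explicit, logged argument.
Two-way ANOVA is out of scope (no two-factor analysis in the target
workflows). `build_report()` assembles per-condition mean ± SD and n for
every metric, applies the configured tests, and writes CSV + JSON + log.

## Problem sizes and numerical conventions

The recovery suites use the study's own scales: 30 top views per protein
channel for radial mapping, 90 (length) and 30 (coverage) lateral views
for the longitudinal metrics, a 150-centriole fixture with 15 rendered
60° fractures for integrity, 40-cell fields for intensity normalization,
and 1000-replicate null simulations for test calibration. At the default
image sizes (roughly 45–150 px a side) the whole validation battery runs
in a few minutes on one CPU. Degenerate inputs raise typed errors rather
than returning numbers: empty images, centres outside the image, bands
covering the whole barrel, collinear ellipse points, undersampled or
too-short profiles, zero control means.

## Known limitations

Recovered offsets inherit a sub-nanometre curvature bias (documented
above). Length and coverage recovery tolerances are dominated by the
condition's own biological spread, not by the estimator (measurement
error ~1.4 nm SD against a 58 nm biological SD). The break detector's gap
angle is meaningful only down to the PSF's angular footprint at the wall
radius (~20°). Roundness from the nine triplet maxima becomes ill-posed
below axis ratios of ~0.7 under the default PSF; the dense wall-ridge fit
is the supported path there. The tilt proxy cannot distinguish a truly
elliptical centriole from an oblique view — that distinction needs 3-D
information that single top views do not carry.
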