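---
title: "Quantifying planar cell polarity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar cell polarity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpquant)
library(dplyr)
```

pcpquant implements four quantitative readouts of planar cell polarity
(PCP) in developing skin, together with a synthetic-data module that
generates every input type with known ground truth. This vignette explains
each estimator, its assumptions, the tunable parameters, and the design
choices made where the underlying procedures are conventionally left
unspecified.

## Conventions

All angles are in degrees with **anterior = 0**, increasing
counterclockwise in a right-handed frame (x right, y up). Because image
row indices increase *down* the screen, every angle computed from pixel
coordinates negates the row axis; `pixel_angle()` is the single place this
is done. Pixel coordinates are 0-based with x = column and y = row; a
pixel's center sits at half-integer coordinates. Polygon ROIs rasterize
under a half-open pixel-center rule (a pixel belongs to a polygon iff its
center does, with boundary crossings assigned to the high side), so an
axis-aligned w-by-h rectangle covers exactly `w * h` pixels.

Inputs for the nematic-order analysis are assumed pre-rotated so the
anterior–posterior axis is horizontal; `rotate_image_90()` is provided for
quarter-turn alignment and for rotation-equivariance checks.

## Hair-follicle polarity

A developing hair follicle images as a P-cadherin-high anterior cluster
and a Sox9+ posterior progenitor domain. In a *polarized* follicle the
Sox9 domain forms a crescent offset from the P-cadherin core, and the
vector from the Sox9 centroid to the P-cadherin centroid points along the
growth direction; an *unpolarized* follicle shows a concentric Sox9 ring
around a central P-cadherin cluster (the "bicycle wheel").

`segment_follicles()` thresholds each channel (Otsu by default; a fixed
threshold is available for calibrated data), labels connected components,
discards those under `min_area` (default 50 px), and pairs each
P-cadherin component with the nearest Sox9 component within
`pairing_radius` (default 3x the median component equivalent radius).
Unpaired components are reported with a QC flag, never silently dropped —
this replaces interactive hand-correction with a reviewable flag export.

`classify_follicles()` computes two geometric signatures per follicle:

* **coverage** — the angular extent of Sox9 pixels about the P-cadherin
  centroid, measured as occupied bins of `bin_width` (default 10) degrees;
* **offset ratio** — distance between the two marker centroids divided by
  the follicle radius estimate.

A follicle is non-polarized when `coverage >= 300` degrees *or*
`offset_ratio < 0.15`; otherwise it is polarized with growth angle the
direction from the Sox9 centroid to the P-cadherin centroid. The two
cutoffs are configurable; the defaults sit halfway between the synthetic
phenotype extremes (a 120-degree crescent scores coverage ~120 and offset
ratio ~0.6; a full ring scores 360 and ~0). They are geometric signatures
of the phenotypes rather than a reconstruction of any particular legacy
script, whose decision rule is not public.

`summarize_calls()` reports the percent polarized, the circular mean and
resultant of polarized angles (first trigonometric moment), and a
rose-histogram (default 20-degree bins) for `plot_rose()`.

## Per-cell nematic order

For a membrane protein in one cell, polarity is the intensity-weighted
second circular moment over the cell's boundary pixels:

$$Q = \frac{\sum_p I_p\, e^{\,2 i \varphi_p}}{\sum_p I_p},\qquad
\text{magnitude} = |Q| \in [0,1],\quad
\text{axis} = \tfrac{1}{2}\arg Q \in [0^\circ, 180^\circ).$$

Doubling the angle makes the measure axial: signal at φ and φ+180
reinforces, which is the correct symmetry for junctional enrichment along
an axis. The weighting is per boundary *pixel* (not per junction
segment): this is exactly testable against a brute-force pixel sum and
matches the published description of the nematic-order convention.
Whether legacy tools weighted by edge segments instead is not
documented; the pixel convention is ours and is stated in the output.

`extract_boundary_pixels()` takes the cell's outline (pixels with a
4-neighbor outside) plus `ring_width - 1` inward dilations (default
`ring_width = 2`). Cells touching the image border have truncated bands
and are flagged and excluded from tissue aggregates by default.
`aggregate_polarity()` averages the per-cell nematic vectors
`magnitude * exp(2i * axis)`; the modulus of that mean is a coherence
measure (it is 0 for randomly oriented cells even when each cell is
strongly polar), and an axial histogram (15-degree bins) feeds
`plot_polarity_histogram()`.

Segmentation itself is an input: the package consumes label masks from
any external segmentation tool.

## Junction enrichment

`junction_enrichment()` scores how concentrated a marker is at a
cell-cell junction:

$$JE = \frac{\text{mean junction-ROI intensity}}
           {\text{mean cell (or cell-pair) ROI intensity}}$$

with both means taken after subtracting the mean of a background ROI
(`background_correct()`; negative corrected values are clipped at zero by
default, a documented and togglable choice). JE is invariant to detector
gain and to any offset fully captured by the background ROI. The cell ROI
may be a *contour* band along the pair's periphery or a *filled*
footprint; the two conventions give different expected values (a filled
ROI dilutes the denominator with cytoplasmic pixels), so the style is
carried through to the output. Distributions of JE scores between
conditions are compared with the two-sample Kolmogorov–Smirnov test
(`compare_groups()`).

## FRAP

Raw traces carry three ROI series: the bleached spot, a non-bleached
reference, and an extracellular background. The chain is:

1. **Correction** (`frap_correct()`):
   `corrected = (bleach - background) / [(reference - background) /
   mean_pre(reference - background)]` — background subtraction plus
   compensation of acquisition photobleaching by the reference ROI,
   renormalized to its own pre-bleach mean.
2. **Normalization** (`frap_normalize()`):
   `(F_t - F_bleach) / (F_ini - F_bleach)`, where `F_ini` is the mean
   corrected pre-bleach intensity and `F_bleach` the corrected intensity
   at the first post-bleach frame; the output is 0 at that frame, 1 at
   the pre-bleach level, and starts at `t = 0` (the first post-bleach
   frame — required for the fitted `Y0` to mean the post-bleach
   intercept).
3. **Fitting** (`fit_recovery()`): one-phase association
   `Y(t) = Y0 + (Plateau - Y0)(1 - e^{-k t})` by bounded
   Levenberg–Marquardt least squares (`Y0` in [-0.2, 1], `Plateau` in
   [-0.2, 1.5], `k` in (0, 10] /s), with multi-start initialization — `k`
   seeded from the observed half-recovery time and a x0.2 / x5 bracket.
   `r^2 = 1 - SS_res / SS_tot`; fits with `r^2 <= 0.93` are flagged
   (`low_r2`) but reported, and a constant series is returned exactly as
   a flat fit. Optimizer failure yields `converged = FALSE` with a flag,
   never a silent number.
4. **Immobile fraction**: `1 - (Plateau - Y0) / (1 - Y0)`, clipped to
   [0, 1] with a warning when a fitted Plateau strays outside the
   physical range.

`frap_summarize()` produces both estimators: the fit of the per-timepoint
*averaged* trace (the headline, matching how mean recovery curves are
conventionally fitted) and per-trace fits for dispersion. Averaging
requires a common time grid; resampling is out of scope. Whether
poorly-fitting individual traces should be excluded before averaging is
not standardized; the package averages all traces and lets the per-trace
QC flags inform exclusion by the caller.

## The synthetic-data module

Each generator emits its fixture plus a ground-truth table, so every
estimator is validated by recovery rather than by eyeballing.

**Follicles** (`sim_follicle_image()`): non-overlapping follicles (center
separation > 2 radii, rejection-sampled with a bounded retry budget) with
a P-cadherin disc (radius 6 px) and either a full Sox9 annulus
(unpolarized) or an annular arc of `crescent_width` (default 120) degrees
centered opposite a growth angle drawn from von Mises(μ, κ) — the
standard unimodal circular family; the sampler is a Best–Fisher rejection
scheme. Signal (200 units) is additive over a constant background
(30 units) with i.i.d. Gaussian noise; this is the simplest noise model
that supports exact noiseless checks. Defaults emulate a backskin field
at moderate SNR; real images add uneven illumination, follicle-stage
variation and out-of-focus light that the generator deliberately omits,
so passing tests demonstrate estimator correctness, not robustness to
every imaging pathology.

**Cell meshes** (`sim_cell_mesh()`): Voronoi tessellation of a jittered
*hexagonal* lattice. The lattice geometry is load-bearing: hexagonal cell
symmetry (6-fold) cannot leak into the 2nd circular moment, whereas a
square lattice's 4-fold shape anisotropy biases the recovered axis by
several degrees. Membrane signal is a Gaussian transverse profile
(σ = `membrane_width / 2`, default width 5 px, truncated at 3σ) of the
*exact* Euclidean distance to the Voronoi boundary, computed from the
bisector geometry. Both choices are anti-aliasing measures: a binary
raster band deposits systematically more pixels on slanted than on
axis-aligned edges and contaminates the nematic moment by up to ~0.1 in
magnitude. With the defaults (`jitter_frac = 0.03`), interior cells of an
unmodulated mesh carry spurious magnitude below 0.05, and a modulated
mesh returns the tissue mean axis to within a small fraction of a degree.
Per-cell axes still vary by a few degrees — that is genuine cell-shape
anisotropy interacting with the modulation, not estimator error, and it
mirrors what irregular real cells do.

**Cell pairs** (`sim_cell_pair()`): two rectangular footprints sharing a
vertical junction; the periphery band carries membrane signal, the shared
band `enrichment_factor` times as much, both additive over background.
The returned cell ROI is the *periphery excluding the junction* — the ROI
drawn along the outside of the pair naturally excludes the shared edge —
so the noiseless JE equals the generator's enrichment factor exactly.

**FRAP traces** (`sim_frap_traces()`): the standard sequence — 3
pre-bleach frames, an instantaneous bleach occupying 5.9 s of dead time
(no samples during the bleach), then 60 frames at 5-s intervals. The
bleach ROI follows
`background + S·D(t)·[(1 - depth) + depth·mobile·(1 - e^{-kt})]` with a
shared acquisition-bleaching factor `D(t) = e^{-βt}` applied to all
fluorescent ROIs (a single exponential, since one reference ROI is used
to correct it). `signal_level` (default 1000) sets the camera scale; on
the normalized scale the noise sd is `noise_sd / (signal_level·depth)`.

## Numerical choices and degenerate inputs

* Angle seams: values within 1e-9 of the period wrap to 0, so axes are
  always in [0, 180) and directions in [0, 360).
* Flat channels threshold to empty foreground (warning, empty result);
  empty ROIs, missing cell IDs, non-positive references, and zero bleach
  depth are hard errors naming the offending object.
* Zero-signal or tiny boundary bands yield flagged NA polarity, never a
  number.
* Problem sizes used in the shipped validation: 200 follicles in a
  1600-px field, ~100-cell meshes in a 300-px domain, 50 FRAP traces of
  63 frames — sizes at which every recovery statistic is stable at desk
  scale.

## Known limitations

* No optics: the generators use additive Gaussian noise and a crude
  Gaussian membrane profile, not PSF convolution or photon statistics.
* Follicle analysis is 2-D on projections; vertically growing follicles
  viewed end-on are classified by ring geometry only.
* The polarized/non-polarized decision rule reproduces the described
  phenotypes but is not guaranteed identical to legacy in-house criteria,
  which are unpublished.
* FRAP fitting is single-component; reaction–diffusion kinetics and
  two-phase recoveries are out of scope.
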