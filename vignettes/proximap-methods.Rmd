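---
title: "Methods: quantifying visual and prosthetic cortical activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying visual and prosthetic cortical activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`proximap` analyses intrinsic optical-imaging recordings of primary
visual cortex responding to visual stimuli and to sub-retinal
micro-electrode stimulation.  This vignette documents the models and
procedures, the parameters that matter, the numerical choices that were
genuinely open, and what the synthetic-data tests do and do not
establish about real recordings.

## Conventions

Image coordinates are 1-based `(row, col)`, rows increasing downward.
Physical positions are pixels × `pixel_pitch` (mm).  Directions have
angle `atan2(-Δrow, Δcol)` in degrees, so 0° points along +col and
angles increase counterclockwise on the displayed image.  Ellipse and
activation orientations are *axial* (undirected): degrees in [0, 180),
differences folded into [0, 90].  All orientation arithmetic goes
through `axial_angle()` / `axial_difference()` so that 179° and 1°
are 2° apart, never 178°.

## Signal model and preprocessing

Intrinsic signals are fractional reflectance changes; an activation is a
negative-going "initial dip" of order 0.1–2 % on the baseline.  The
synthetic generator therefore builds trials as

  baseline 1.0 × (1 + amplitude · spatial Gaussian · temporal profile) + shared artifact(t) + noise,

with a multiplicative dip so both normalizations downstream (z-score and
ΔI/I) are meaningful.  The temporal profile is a 0.5 s linear rise, a
plateau to 2.5 s after onset, then exponential decay with τ = 1 s; the
recordings fix only the analysis window (static maps average 1.5–2.5 s
after onset), not the true dynamics, so the profile is a package choice
that keeps the window on the plateau.

Preprocessing follows three steps:

1. `subtract_border_trend()` — the spatial mean time course of the outer
   2-pixel border ring is subtracted from every pixel.  The subtracted
   course is centered on its temporal mean: the step removes the shared
   temporal pattern but not the DC level, so an artifact-free stack
   passes through unchanged.
2. `temporal_normalize()` — per trial and pixel, subtract the mean and
   divide by the sd of the pre-stimulus ("frame 0") window, defined as
   all frames before stimulus onset (0.5 s into the trial).  Pixels with
   zero pre-stimulus variance are zeroed and flagged in a `"masked"`
   attribute rather than producing non-finite values.  This makes the
   pipeline invariant to per-pixel affine rescaling of the raw data.
3. `compute_static_zscore_map()` — static maps average the normalized
   frames over the 1.5–2.5 s window and over trials; the blank static
   map is subtracted pixel by pixel and the result divided by the blank
   standard deviation *over space*.  The wording of the normalization
   admits a scalar or per-pixel sd; the scalar spatial sd is the
   default, a per-pixel (across blank trials) variant is available via
   `analysis_config(blank_sd = "temporal")`.

ΔI/I maps (`compute_dii_map()`) use the standard first-frames division
per trial, blank subtraction frame by frame, and the same static window;
they operate on the raw stacks, not the z-scored ones.

Activation regions are extracted from a smoothed map: convolution with a
15 × 15 flat kernel whose edge pixels are renormalized (each output is
the mean of in-image pixels under the window), then thresholding at
z ≤ −3.09 — the dip is negative, so activation is the lower tail.  The
threshold value is the published convention and is kept as printed (note
Φ(−3.09) ≈ 0.001, not 0.01).  Smoothing is used *only* for contouring;
centers of mass and amplitudes are measured on the unsmoothed z map.
Connected components use 8-connectivity; the largest component is "the"
activation, all components are retained, and an empty region is an
explicit valid outcome, not an error.

## Shape and position descriptors

`equivalent_ellipse()` is the ellipse with the same normalized second
central moments as the binary region, each pixel contributing a unit
square (the 1/12 variance term); axis lengths are `4·√eigenvalue`, the
equivalent diameter is that of the equal-area circle, and the aspect
ratio √(λ₁/λ₂).  Degenerate (collinear) regions get a one-pixel
minor-axis floor and a flag.  The center of mass is the |z|-weighted
centroid over the thresholded region (weighting by thresholded |z| is
one of two defensible readings; the alternative — raw z over the whole
map — is dominated by noise pixels).

Polar maps assign each pixel the response-weighted centroid of the
stimulus grid positions, with responses rectified to the activation sign
(`max(0, −z)`); the expected cortical position of a visual location is
the responsive pixel whose (azimuth, elevation) preference is nearest —
the intersection of the two cardinal maps.  Positional error is the
Euclidean distance between expected position and measured center of
mass, reported in mm and in degree-equivalents (mm / magnification).
Cortical magnification is fitted on azimuth displacements by default.

A caveat the synthetic tests make explicit: when activation extent
exceeds the grid spacing (as with 20° stimuli at ~22 µm/° magnification)
neighboring responses overlap and the preference map is compressed
toward the grid center, biasing expected positions outward at the grid
edge.  The pixel-level round-trip identity therefore holds for
non-overlapping activations (tested with narrow generator blobs); with
realistic overlap the polar maps remain monotone and usable but carry
that compression, as real maps do.

## Intensity response

`fit_naka_rushton()` fits `R(c) = Rmax·cⁿ/(cⁿ + C50ⁿ)` by bounded
Levenberg-Marquardt least squares with multi-start (C50 over the
intensity quartiles, n ∈ {1, 2, 4}), which is robust for the 5–7 point
series this assay produces; an optional additive baseline is off by
default.  The 10–90 % operational range is the closed form
`C50·(9^(1/n) − 9^(−1/n))`, cross-checked in the tests against numeric
root finding of R = 0.1·Rmax and 0.9·Rmax to 1e-6 relative error.
`equivalent_intensity()` inverts the fitted visual-luminance function to
express electrically evoked amplitudes as equivalent luminance;
amplitudes at or above Rmax are flagged saturated.

## The two-source retinal activation model

Electrical stimulation of the retina activates (i) tissue around the
electrode through passive diffusion and (ii) ganglion-cell axons passing
over the electrode en route to the optic disk, which recruits somata
located in a "shadow cone" on the far side of the stimulation site.  On
an N × N grid of retinal space (defaults N = 400, optic disk (200, 100),
electrode (200, 150), so the disk-electrode axis runs along +col):

* `iso_activation()`: 1 where the distance d to the electrode is below
  the electrode radius S, `exp(−d²/(2(σS)²))` beyond (σ = 1 default).
  As defined the surface is discontinuous at d = S (dropping to
  e^(−1/2)); this is kept as printed, with a continuous variant behind
  `continuous = TRUE`.  Where the defining expressions conflate d and
  d², they are read dimensionally: comparisons against S use the
  Euclidean distance, Gaussian exponents use d²/(2·scale²).
* `en_passant_activation()`: `EP = Att·Sig·Cone` with
  `Att = exp(−(d−S)²/(2N²))` (weak large-scale attenuation),
  `Sig = logistic((d_OD − D)/(S/4))` (D = electrode-to-disk distance;
  ≈0 at eccentricities nearer the disk than the electrode, ≈1 beyond —
  somata of activated axons lie at larger eccentricities), and
  `Cone = exp(−(θ/Ω)²/(2σ²))` where θ is the unsigned angle at the disk
  from the disk-electrode axis and Ω = 2·asin(S/D) the cone angle
  subtended by the electrode.  The angular term is defined on the
  half-plane on the electrode side of the disk (positive projection on
  the axis) and zero behind it.
* `combine_activation()`: the weighted sum `IsoA + α·EP`, α ∈ [0, 1].

`model_shape_metrics()` thresholds the combined map at the half-maximum
contour and measures extents along (radial) and perpendicular to
(tangential) the disk-electrode axis; AR = radial / tangential.
**Contour reference — an open design point.**  Both component fields are
unit-normalized, so the model's activation scale is 1 and the
half-maximum contour sits at 0.5 in absolute units (the default,
`reference = "scale"`).  The alternative — half of the *observed* map
maximum — is exposed as `reference = "max"` but is not the default for a
structural reason: wherever the flat top overlaps the rising sigmoid
gate the weighted sum reaches ≈ 1 + α regardless of S, so a
0.5·observed-max contour hugs that overlap ridge, suppresses the
shadow-cone wedge entirely, and loses the tangential-elongation regime
the model exists to predict.  Under the default convention the model
produces its two signature predictions, which the acceptance script
recomputes: radial elongation (AR > 1) for small electrodes (S ≤ 7) and
tangential elongation (AR < 1) for the largest (S = 30).

Two finite-grid effects worth knowing: (i) AR falls strictly with cone
angle through S = 20, but once the tangential extent saturates the
400-pixel grid (S ≥ 20 at α = 1) the ratio plateaus and can tick up
slightly; (ii) AR is not strictly monotone in α — near α = 0 the region
is a near-circular disk whose AR jitters within discretization (±~8 %),
and at high α the wedge *widens* as more of it crosses threshold, so
the elongation statement tested is the qualitative one: AR > 1 for
α ≥ 0.5 at small S, and AR(α = 1) > AR(α = 0.1).

The shadow-cone angle of a physical configuration is
`2·asin((z/2)/y)` degrees, with z the actual stimulated active-surface
diameter (mm) and y the distance to the optic disk; substituting the
corrected radius z/2 into the arcsine is the default, a linear-scaling
alternative is available.  The retino-cortical transform integrates the
local magnification `RCM = 1/(aR + b)` (a = 0.7, b = 30 horizontal;
a = 0.4, b = 40 vertical) to `x(R) = (1/a)·log((aR + b)/b)` per axis;
applying it to model maps (`transform_model_map()`, exact analytic
inverse + bilinear sampling) leaves the sign of AR − 1 unchanged, which
the tests verify for both regimes.

## Radial-organization statistics

For a set of elongated activations (inclusion threshold AR > 1.6 when
assembling sets from pipeline output), the deviation of each site is the
axial difference between its orientation and the direction to a
candidate center; `optimize_radial_center()` exhaustively searches a
grid (default: the sites' bounding box padded 1 unit at 0.1 mm
resolution — the resolution is a package choice) for the minimizing
position, with ties broken deterministically in row-major order.  The
Monte-Carlo null replaces orientations with i.i.d. uniform axial angles
(uniformity on [0, 180) is the natural null and the assumed one),
re-optimizes the center per draw — the optimization is *inside* the
loop, so the null accounts for the selection effect of choosing the best
center — and records the minimized median deviation; 1000 iterations is
the package default.  `gaussian_p()` reports the empirical lower-tail
area and the Gaussian tail from the null's mean and sd (the null is
near-normal; both are reported and agree in tests), plus
`z = (mean − observed)/sd`.  Center-of-mass anisotropy expresses each
site's (center of mass − geometric center) offset as a signed angle in a
frame pointing at the radial center, ±180° meaning displacement directly
away; the circular mean summarizes the set.  `align_and_average_maps()`
rotates each map (bilinear, about the activation center) so its radial
axis points right, centers it, averages, and reports a secondary contour
at z = −4.5.

## Problem sizes and reproducibility

Generator defaults emulate the recording conditions: 8 s trials at
33.3 Hz, stimulus onset at 0.5 s, a 5 × 5 mm window at 100 × 100 pixels
(0.05 mm/pixel), 20 trials per condition, the 5 × 4 grid of 20° squares
at 20° spacing, the luminance series [2, 13.75, 25.5, 37.25, 49] cd/m²
with a Naka-Rushton law (Rmax 0.015 fractional, C50 9.6, n 6.05), and
pixel noise defaulting to 0.2 × the dip amplitude.  The test-suite and
demo pipeline use explicitly reduced geometries chosen by the package —
40 × 40 pixels at 0.125 mm/pixel (the same 5 mm field), 10 Hz × 4 s
trials, 8 trials, Monte-Carlo nulls of 100–200 iterations on 0.25 mm
search grids — so that full runs complete in seconds; every reduction is
passed as an explicit argument, never by changing the defaults.  All
randomness flows through explicit `seed` arguments (restoring the
caller's RNG state); `run_pipeline()` writes a manifest whose hash
covers the scientific configuration, and identical configurations
reproduce outputs bit-identically.

What the synthetic tests show — and do not.  They establish that every
stage recovers its own ground truth at the stated tolerances (exact at
zero noise; center within pixels and AR within ~10 % at recording-like
noise), that the statistics are calibrated (false-positive region rate
≤ 1 % at the −3.09/smoothing convention; null p-values roughly uniform),
and that the model predictions are as described.  They do not establish
performance on real recordings: the generator has i.i.d. Gaussian pixel
noise and i.i.d. trials (no heartbeat or vasomotor structure, no
spatially correlated noise, no vessel artifacts), Gaussian activation
profiles, and no hemodynamic nonlinearity.  Inter-trial variability
structure in particular is unknown for the real data and assumed
independent here.

## Known limitations

* No motion correction, vessel masking, or hemodynamic deconvolution.
* The blank spatial-sd normalization makes z values comparable within a
  session but not across cameras with different noise floors.
* The model is functional, not biophysical: no cable-model thresholds,
  no finite-element field simulation; its predictions are shape trends,
  not absolute extents.
* Published per-animal population averages (magnification 22 µm/°, size
  slope 81 µm/°, per-animal Naka-Rushton means, the observed 13.3°
  deviation) derive from recordings that are not deposited; the package
  reproduces the formulas and the desk-scale model predictions, and
  covers the rest by parameter-recovery suites on synthetic data.
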