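# proximap

Quantitative analysis of cortical population maps evoked by **visual**
versus **sub-retinal prosthetic** stimulation, as recorded with intrinsic
optical imaging of rat primary visual cortex (V1).

Retinal prostheses restore some vision, but the cortical activation a
single electrode evokes is typically far larger and more elongated than
the activation of the visual stimulus it is meant to replace.  `proximap`
implements the full analysis chain needed to quantify that mismatch and
to explain it:

* **Preprocessing** of multi-frame imaging trials: border-ring artifact
  removal, frame-0 (pre-stimulus) temporal normalization, blank-based
  static **z-score maps** and **ΔI/I maps** (1.5–2.5 s post-onset window),
  flat-kernel smoothing and thresholding at z ≤ −3.09 into activation
  regions.
* **Map statistics**: |z|-weighted center of mass, the **equivalent
  ellipse** (second central moments → extent, aspect ratio, axial
  orientation), retinotopic **polar maps** with expected-position lookup,
  positional error in mm and degree-equivalents, cortical magnification
  (mm/°) and size-tuning fits.
* **Intensity response**: Naka-Rushton fits
  `R(c) = Rmax·cⁿ/(cⁿ + C50ⁿ)`, the 10–90 % **operational range**
  `C50·(9^(1/n) − 9^(−1/n))`, and equivalent-luminance mapping of
  electrical amplitudes.
* **Two-source retinal activation model**: an isotropic flat-top Gaussian
  spread around the electrode plus an **axons-en-passant shadow cone**
  (attenuation × sigmoid eccentricity gate × angular cone), combined as
  `IsoA + α·EP`; shape metrics along/perpendicular to the optic-disk
  axis, the shadow-cone angle `2·asin((z/2)/y)`, and a retino-cortical
  transform integrating `RCM = 1/(aR + b)`.
* **Radial-organization statistics**: the cortical position optimizing
  the radial arrangement of elongated activations, a Monte-Carlo null of
  uniform orientations at the observed positions, Gaussian/empirical
  p-values, center-of-mass anisotropy, and radially aligned map
  averaging.
* A **synthetic-data generator** emulating the recordings (negative
  "initial dip" blobs on a baseline of 1, shared border artifact, i.i.d.
  pixel noise, retinotopy grids, Naka-Rushton intensity series, radially
  organized elongated sets) so the whole pipeline is testable end to end
  with known ground truth.

## Worked example

```r
library(proximap)

acq <- acquisition_config(frame_rate = 10, trial_duration = 4,
                          image_rows = 40, image_cols = 40,
                          pixel_pitch = 0.125, n_trials = 8)
spec <- activation_spec(center = c(20, 28), sigma_major = 5, sigma_minor = 3,
                        orientation = 30, amplitude = -0.015)
stim  <- generate_trial_stack(acq, spec, noise_sd = 0.003, seed = 1)
blank <- generate_trial_stack(acq, activation_spec(c(20, 20), amplitude = 0),
                              noise_sd = 0.003, seed = 2)

pre <- function(s) temporal_normalize(subtract_border_trend(s, 2))
z   <- compute_static_zscore_map(pre(stim), pre(blank))
reg <- extract_activation(z, analysis_config(smooth_kernel = 5))
reg
#> Activation region: 204 px (largest of 1 component(s))
center_of_mass(z, reg)
#>      row      col
#> 19.94337 28.06149
equivalent_ellipse(reg, acq$pixel_pitch)
#> Equivalent ellipse: center (20.0, 28.0) px, axes 2.471 x 1.651,
#> eq. diameter 2.015, AR 1.50, orientation 31.3 deg
```

The ground truth (center (20, 28), orientation 30°, anisotropy 5:3) is
recovered within a fraction of a pixel and a degree; the ellipse axes are
in mm via `pixel_pitch`.

The retinal activation model predicts how the activation shape depends on
electrode size — radially elongated for a small electrode (narrow shadow
cone), tangentially elongated for a large one:

```r
model_ar_sweep(c(5, 30), alpha_values = 1)
#>    S alpha cone_angle_deg       ar   extent
#> 1  5     1       11.47834 2.115702 158.2951
#> 2 30     1       73.73980 0.737500 381.0866
```

`ar` is the radial-over-tangential extent ratio of the half-maximum
contour: 2.12 (> 1, radial) at S = 5 against 0.74 (< 1, tangential) at
S = 30.

The radial-organization test, evaluated on published summary statistics
(null mean 23.6°, sd 4.9°, observed median deviation 13.3°):

```r
p <- gaussian_p(list(mean = 23.6, sd = 4.9), observed = 13.3)
#> z = 2.10, p = 0.018
deg_to_mm(20, magnification = 0.022)
#> 0.44  # mm of cortex spanned by a 20 deg stimulus at 22 um/deg
```

A full demonstration run (simulate → preprocess → measure → fit → model
→ radial → report) from a single config:

```r
cfg <- read_run_config(system.file("extdata", "demo_run.yaml",
                                   package = "proximap"))
cfg$out <- "demo-out"
run_pipeline(cfg)   # writes metrics.csv, fits.json, model_sweep.csv,
                    # radial.json, size_ar_summary.csv, manifest.json
```

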