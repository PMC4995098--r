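# Synthetic-data generators.  They emulate the statistical structure of
# intrinsic-imaging recordings of V1 -- a multiplicative negative-going
# "initial dip" on a baseline of 1, a shared slow additive artifact
# measurable on the image border, and i.i.d. pixel noise -- so that every
# downstream stage can be exercised against known ground truth.

# Anisotropic Gaussian spatial profile of an activation, peak 1 at center.
blob_profile <- function(spec, rows, cols) {
  rc <- expand_rc(rows, cols)
  dr <- rc$r - spec$center[1]
  dc <- rc$c - spec$center[2]
  u <- axis_vector(spec$orientation)            # major axis
  v <- c(u[2], -u[1])                           # minor axis
  pu <- dr * u[1] + dc * u[2]
  pv <- dr * v[1] + dc * v[2]
  matrix(exp(-(pu^2 / (2 * spec$sigma_major^2) +
               pv^2 / (2 * spec$sigma_minor^2))), rows, cols)
}

expand_rc <- function(rows, cols) {
  list(r = matrix(seq_len(rows), rows, cols),
       c = matrix(seq_len(cols), rows, cols, byrow = TRUE))
}

# Rise / plateau / exponential-decay time course, 0 before stimulus onset,
# peak 1.
temporal_profile <- function(spec, acq) {
  t <- acq_times(acq) - acq$stim_onset
  tau <- numeric(length(t))
  rising <- t >= 0 & t < spec$rise_time
  tau[rising] <- t[rising] / max(spec$rise_time, .Machine$double.eps)
  plateau <- t >= spec$rise_time & t <= spec$plateau_until
  tau[plateau] <- 1
  decay <- t > spec$plateau_until
  tau[decay] <- exp(-(t[decay] - spec$plateau_until) / spec$decay_tau)
  tau
}

# Slow global artifact time course, unit peak, scaled by amp.
border_artifact_course <- function(acq, amp) {
  amp * sin(2 * pi * acq_times(acq) / acq$trial_duration)
}

#' Generate a synthetic imaging trial stack
#'
#' Builds `n_trials` trials of frames on a baseline of 1.0 carrying a
#' multiplicative Gaussian dip (peak fractional amplitude
#' `spec$amplitude` at `spec$center`, rise/plateau/decay time course), a
#' slow additive artifact time course shared by all pixels (and hence
#' measurable on the outer border), and i.i.d. Gaussian pixel noise.
#'
#' @param acq An [acquisition_config()].
#' @param spec An [activation_spec()]; use `amplitude = 0` for a blank.
#' @param noise_sd Pixel noise standard deviation (>= 0).
#' @param border_artifact_amp Peak amplitude of the shared additive
#'   artifact.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param n_trials Number of trials; defaults to `acq$n_trials`.
#' @return A [trial_stack()] whose `truth` field stores `spec`.
#' @export
generate_trial_stack <- function(acq, spec, noise_sd = 0,
                                 border_artifact_amp = 0, seed,
                                 n_trials = acq$n_trials) {
  stopifnot(inherits(acq, "acquisition_config"),
            inherits(spec, "activation_spec"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (spec$center[1] < 1 || spec$center[1] > acq$image_rows ||
      spec$center[2] < 1 || spec$center[2] > acq$image_cols)
    stop("activation center lies outside the image")
  nf <- acq$n_frames; nr <- acq$image_rows; nc <- acq$image_cols
  w <- blob_profile(spec, nr, nc)
  tau <- temporal_profile(spec, acq)
  g <- border_artifact_course(acq, border_artifact_amp)
  base <- 1 + spec$amplitude * outer(tau, w) + array(g, c(nf, nr, nc))
  data <- array(0, c(n_trials, nf, nr, nc))
  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      noise <- if (noise_sd > 0)
        array(stats::rnorm(nf * nr * nc, sd = noise_sd), c(nf, nr, nc))
      else 0
      data[tr, , , ] <- base + noise
    }
  })
  acq2 <- acq
  acq2$n_trials <- n_trials
  trial_stack(data, acq2, truth = spec)
}

#' Generate a retinotopy-mapping session
#'
#' Emulates a 5 x 4 grid of flashed square stimuli: each grid position
#' evokes a Gaussian dip whose cortical center is displaced from the
#' reference pixel (image center, representing visual (0, 0)) by the
#' visual offset times the cortical magnification.  Azimuth maps along
#' +col, elevation along -row.
#'
#' @param acq An [acquisition_config()].
#' @param grid_azimuth,grid_elevation Stimulus center positions in degrees
#'   (defaults: 5 azimuths x 4 elevations, 20 deg apart).
#' @param stim_size_deg Stimulus side length in degrees.
#' @param magnification Cortical magnification in mm/deg (> 0).
#' @param size_slope Cortical extent per degree of stimulus size, mm/deg;
#'   sets the blob sigma via `size_deg * size_slope / 2.355` (FWHM ~
#'   activation diameter).
#' @param amplitude Peak fractional dip amplitude (negative).
#' @param noise_sd Pixel noise sd.
#' @param border_artifact_amp Shared artifact amplitude.
#' @param seed Integer seed.
#' @return A [session_bundle()]; stack `truth` fields hold the ground
#'   truth, and the bundle carries `reference_pixel` and `magnification`
#'   attributes.
#' @export
generate_retinotopy_session <- function(acq,
                                        grid_azimuth = seq(-40, 40, by = 20),
                                        grid_elevation = seq(-30, 30, by = 20),
                                        stim_size_deg = 20,
                                        magnification = 0.022,
                                        size_slope = 0.081,
                                        amplitude = -0.015,
                                        noise_sd = 0.2 * abs(amplitude),
                                        border_artifact_amp = 0,
                                        seed = 1) {
  if (magnification <= 0) stop("magnification must be positive")
  ref <- c((acq$image_rows + 1) / 2, (acq$image_cols + 1) / 2)
  grid <- expand.grid(elevation = grid_elevation, azimuth = grid_azimuth)
  sigma_px <- stim_size_deg * size_slope / 2.355 / acq$pixel_pitch
  stacks <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    ctr <- c(ref[1] - grid$elevation[k] * magnification / acq$pixel_pitch,
             ref[2] + grid$azimuth[k] * magnification / acq$pixel_pitch)
    if (ctr[1] < 1 || ctr[1] > acq$image_rows ||
        ctr[2] < 1 || ctr[2] > acq$image_cols)
      stop("grid position maps outside the image; shrink the grid or ",
           "increase the field of view")
    spec <- activation_spec(ctr, sigma_major = sigma_px,
                            amplitude = amplitude)
    stacks[[k]] <- generate_trial_stack(acq, spec, noise_sd,
                                        border_artifact_amp,
                                        seed = seed + k)
    stacks[[k]]$condition_label <-
      sprintf("az%+g_el%+g", grid$azimuth[k], grid$elevation[k])
  }
  blank <- generate_trial_stack(acq, activation_spec(ref, amplitude = 0),
                                noise_sd, border_artifact_amp,
                                seed = seed, n_trials = acq$n_blank_trials)
  blank$condition_label <- "blank"
  meta <- data.frame(label = vapply(stacks, `[[`, "", "condition_label"),
                     type = "visual",
                     position_deg_x = grid$azimuth,
                     position_deg_y = grid$elevation,
                     size_deg = stim_size_deg,
                     luminance_cd_m2 = 49,
                     current_uA = NA_real_)
  out <- session_bundle(stacks, blank, meta)
  attr(out, "reference_pixel") <- ref
  attr(out, "magnification") <- magnification
  out
}

#' Generate an intensity-series session
#'
#' Condition amplitudes follow a Naka-Rushton law
#' `Rmax * c^n / (c^n + C50^n)` of the stimulus level, as a dip of that
#' fractional amplitude at a fixed cortical position.
#'
#' @param acq An [acquisition_config()].
#' @param nr Named list with `Rmax` (peak fractional dip magnitude),
#'   `C50` and `n`; defaults emulate the visual luminance response.
#' @param levels Stimulus intensities, non-negative and ascending
#'   (defaults: the luminance series in cd/m^2).
#' @param center Cortical blob center (defaults to the image center).
#' @param sigma_px Blob sigma in pixels.
#' @param noise_sd Pixel noise sd.
#' @param seed Integer seed.
#' @return A [session_bundle()] whose metadata carries the levels.
#' @export
generate_intensity_series <- function(acq,
                                      nr = list(Rmax = 0.015, C50 = 9.6,
                                                n = 6.05),
                                      levels = c(2, 13.75, 25.5, 37.25, 49),
                                      center = NULL, sigma_px = 8,
                                      noise_sd = 0.003, seed = 1) {
  if (length(levels) == 0) stop("levels must be non-empty")
  if (any(levels < 0) || is.unsorted(levels, strictly = TRUE))
    stop("levels must be non-negative and strictly ascending")
  if (is.null(center))
    center <- c((acq$image_rows + 1) / 2, (acq$image_cols + 1) / 2)
  amp <- -naka_rushton(levels, nr$Rmax, nr$C50, nr$n)
  stacks <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    spec <- activation_spec(center, sigma_major = sigma_px,
                            amplitude = amp[k])
    stacks[[k]] <- generate_trial_stack(acq, spec, noise_sd, 0,
                                        seed = seed + k)
    stacks[[k]]$condition_label <- sprintf("level_%g", levels[k])
  }
  blank <- generate_trial_stack(acq, activation_spec(center, amplitude = 0),
                                noise_sd, 0, seed = seed,
                                n_trials = acq$n_blank_trials)
  blank$condition_label <- "blank"
  meta <- data.frame(label = vapply(stacks, `[[`, "", "condition_label"),
                     type = "intensity",
                     position_deg_x = 0, position_deg_y = 0,
                     size_deg = 20,
                     luminance_cd_m2 = levels,
                     current_uA = NA_real_)
  out <- session_bundle(stacks, blank, meta)
  attr(out, "nr_truth") <- nr
  out
}

#' Elongated activation set
#'
#' Positions and axial orientations of elongated activations, the input of
#' the radial-organization statistics.
#'
#' @param centers n x 2 matrix of (row, col) positions (any consistent
#'   length unit, typically mm).
#' @param orientations Axial orientations in degrees `[0, 180)`.
#' @param ar_values Optional aspect ratios.
#' @param com_offsets Optional n x 2 matrix, center-of-mass minus
#'   geometric center.
#' @return An object of class `elongated_set`.
#' @export
elongated_set <- function(centers, orientations, ar_values = NULL,
                          com_offsets = NULL) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, nrow(centers) == length(orientations))
  if (!is.null(ar_values)) stopifnot(length(ar_values) == nrow(centers))
  if (!is.null(com_offsets)) {
    com_offsets <- as.matrix(com_offsets)
    stopifnot(nrow(com_offsets) == nrow(centers), ncol(com_offsets) == 2)
  }
  structure(list(centers = centers,
                 orientations = axial_angle(orientations),
                 ar_values = ar_values, com_offsets = com_offsets),
            class = "elongated_set")
}

#' @export
print.elongated_set <- function(x, ...) {
  cat(sprintf("Elongated activation set: %d sites\n", nrow(x$centers)))
  invisible(x)
}

#' Generate a radially organized set of elongated activations
#'
#' Sites are placed uniformly in an annulus around a virtual optic-disk
#' representation; each orientation is the radial direction toward the
#' optic disk plus Gaussian axial jitter.  Center-of-mass offsets point
#' away from the optic disk (with the same angular jitter), emulating the
#' anisotropy expected from axons-en-passant recruitment.
#'
#' @param n_sites Number of sites (>= 3).
#' @param od_position (row, col) of the optic-disk representation.
#' @param eccentricity_range Length-2 vector, annulus inner/outer radius
#'   (same units as `od_position`).
#' @param angular_jitter_sd Axial jitter sd in degrees.
#' @param com_offset_mag Magnitude of the center-of-mass offsets.
#' @param seed Integer seed.
#' @return An [elongated_set()].
#' @export
generate_elongated_set <- function(n_sites = 20, od_position = c(0, 0),
                                   eccentricity_range = c(1, 2.5),
                                   angular_jitter_sd = 10,
                                   com_offset_mag = 0.1, seed = 1) {
  if (n_sites < 3) stop("n_sites must be at least 3")
  stopifnot(length(eccentricity_range) == 2,
            eccentricity_range[1] > 0,
            diff(eccentricity_range) >= 0)
  with_seed(seed, {
    r <- sqrt(stats::runif(n_sites, eccentricity_range[1]^2,
                           eccentricity_range[2]^2))
    phi <- stats::runif(n_sites, 0, 2 * pi)
    centers <- cbind(od_position[1] + r * sin(phi),
                     od_position[2] + r * cos(phi))
    radial <- axial_angle(direction_angle(od_position[1] - centers[, 1],
                                          od_position[2] - centers[, 2]))
    orient <- axial_angle(radial + stats::rnorm(n_sites,
                                                sd = angular_jitter_sd))
    away <- cbind(centers[, 1] - od_position[1],
                  centers[, 2] - od_position[2]) / r
    jit <- stats::rnorm(n_sites, sd = angular_jitter_sd) * pi / 180
    rot <- cbind(away[, 1] * cos(jit) - away[, 2] * sin(jit),
                 away[, 1] * sin(jit) + away[, 2] * cos(jit))
    elongated_set(centers, orient,
                  ar_values = stats::runif(n_sites, 1.6, 2.6),
                  com_offsets = rot * com_offset_mag)
  })
}
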