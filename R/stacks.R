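#' Acquisition configuration
#'
#' Describes the geometry and timing of an intrinsic-imaging recording.
#' Defaults follow the acquisition used throughout: 8 s trials sampled at
#' 33.3 Hz, stimulus onset 0.5 s after trial start (frame 0 window), a
#' 5 x 5 mm cortical window imaged at 100 x 100 pixels, and 20 trials per
#' condition.
#'
#' @param frame_rate Sampling rate in Hz.
#' @param trial_duration Trial length in seconds.
#' @param stim_onset Stimulus onset in seconds from trial start; frames
#'   before this instant form the pre-stimulus ("frame 0") window.
#' @param stim_duration Stimulus duration in seconds.
#' @param image_rows,image_cols Image size in pixels.
#' @param pixel_pitch Pixel size in mm/pixel.
#' @param n_trials Number of stimulated trials per condition.
#' @param n_blank_trials Number of blank trials.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 33.3,
                               trial_duration = 8,
                               stim_onset = 0.5,
                               stim_duration = 1,
                               image_rows = 100,
                               image_cols = 100,
                               pixel_pitch = 0.05,
                               n_trials = 20,
                               n_blank_trials = n_trials) {
  stopifnot(frame_rate > 0, trial_duration > 0,
            stim_onset >= 0, stim_onset < trial_duration,
            image_rows >= 5, image_cols >= 5, pixel_pitch > 0,
            n_trials >= 1, n_blank_trials >= 1)
  n_frames <- floor(trial_duration * frame_rate)
  pre <- sum(frame_times(frame_rate, n_frames) < stim_onset)
  if (pre < 2)
    stop("acquisition must contain at least 2 pre-stimulus frames")
  structure(list(frame_rate = frame_rate, trial_duration = trial_duration,
                 stim_onset = stim_onset, stim_duration = stim_duration,
                 image_rows = image_rows, image_cols = image_cols,
                 pixel_pitch = pixel_pitch, n_trials = n_trials,
                 n_blank_trials = n_blank_trials, n_frames = n_frames),
            class = "acquisition_config")
}

frame_times <- function(frame_rate, n_frames) (seq_len(n_frames) - 1L) / frame_rate

#' Frame times of an acquisition
#'
#' @param acq An [acquisition_config()].
#' @return Numeric vector of frame onset times in seconds (first frame at 0).
#' @export
acq_times <- function(acq) frame_times(acq$frame_rate, acq$n_frames)

#' Pre-stimulus frame indices
#'
#' Indices of the frames acquired strictly before stimulus onset (the
#' "frame 0" window used for temporal normalization and DI/I baselines).
#'
#' @param acq An [acquisition_config()].
#' @return Integer vector of frame indices.
#' @export
prestim_frames <- function(acq) which(acq_times(acq) < acq$stim_onset)

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("Acquisition: %d frames @ %.1f Hz (%.1f s), stim at %.2f s\n",
              x$n_frames, x$frame_rate, x$trial_duration, x$stim_onset))
  cat(sprintf("  image %d x %d px, %.3f mm/px, %d trials (+%d blank)\n",
              x$image_rows, x$image_cols, x$pixel_pitch,
              x$n_trials, x$n_blank_trials))
  invisible(x)
}

#' Ground-truth activation specification
#'
#' Parameters of a synthetic cortical activation: an anisotropic Gaussian
#' "initial dip" (negative fractional reflectance change) with a
#' rise/plateau/decay time course.
#'
#' @param center `(row, col)` of the blob center in pixels (1-based).
#' @param sigma_major,sigma_minor Gaussian extents along the major/minor
#'   axis, in pixels; `sigma_major >= sigma_minor > 0`.
#' @param orientation Axial orientation of the major axis in degrees,
#'   `[0, 180)`, measured from the +column axis (see package conventions).
#' @param amplitude Peak fractional signal change (negative for the dip).
#' @param rise_time Linear rise duration after stimulus onset, s.
#' @param plateau_until Time after onset at which the plateau ends, s.
#' @param decay_tau Exponential decay time constant after the plateau, s.
#' @return An object of class `activation_spec`.
#' @export
activation_spec <- function(center, sigma_major = 6, sigma_minor = sigma_major,
                            orientation = 0, amplitude = -0.01,
                            rise_time = 0.5, plateau_until = 2.5,
                            decay_tau = 1) {
  stopifnot(length(center) == 2, sigma_minor > 0,
            sigma_major >= sigma_minor, rise_time >= 0,
            plateau_until >= rise_time, decay_tau > 0)
  orientation <- orientation %% 180
  structure(list(center = as.numeric(center), sigma_major = sigma_major,
                 sigma_minor = sigma_minor, orientation = orientation,
                 amplitude = amplitude, rise_time = rise_time,
                 plateau_until = plateau_until, decay_tau = decay_tau),
            class = "activation_spec")
}

#' Trial stack container
#'
#' A 4-d array of imaging data, `trials x frames x rows x cols`, with its
#' acquisition metadata, a condition label and (for synthetic data) the
#' generating ground truth.
#'
#' @param data 4-d numeric array, `trials x frames x rows x cols`.
#' @param acquisition An [acquisition_config()] consistent with `data`.
#' @param condition_label Character label.
#' @param truth Optional [activation_spec()] ground truth.
#' @param n_trials_override Internal: accept a trial count differing from
#'   `acquisition$n_trials` (used for blank stacks).
#' @return An object of class `trial_stack`.
#' @export
trial_stack <- function(data, acquisition, condition_label = "cond",
                        truth = NULL, n_trials_override = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 4)
  nt <- if (is.null(n_trials_override)) d[1] else n_trials_override
  if (d[2] != acquisition$n_frames ||
      d[3] != acquisition$image_rows || d[4] != acquisition$image_cols)
    stop("stack dimensions inconsistent with acquisition config")
  if (!all(is.finite(data))) stop("stack contains non-finite values")
  structure(list(data = data, acquisition = acquisition,
                 condition_label = condition_label, truth = truth,
                 n_trials = nt),
            class = "trial_stack")
}

#' @export
print.trial_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Trial stack '%s': %d trials x %d frames x %d x %d px\n",
              x$condition_label, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' @export
dim.trial_stack <- function(x) dim(x$data)

#' Session bundle
#'
#' A set of condition trial stacks sharing one blank condition, with a
#' per-condition metadata table.
#'
#' @param stacks List of [trial_stack()]s (one per condition).
#' @param blank A single blank [trial_stack()].
#' @param metadata `data.frame` with one row per stack; columns include
#'   `label`, `type` and whichever of `position_deg_x`, `position_deg_y`,
#'   `size_deg`, `luminance_cd_m2`, `current_uA` apply.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(stacks, blank, metadata) {
  stopifnot(is.list(stacks), inherits(blank, "trial_stack"),
            is.data.frame(metadata), nrow(metadata) == length(stacks))
  structure(list(stacks = stacks, blank = blank, metadata = metadata),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("Session: %d conditions + blank (%s)\n", length(x$stacks),
              paste(unique(x$metadata$type), collapse = ", ")))
  invisible(x)
}

#' Write / read a trial stack on disk
#'
#' The frame data (trial-averaged pages) go to a multi-page 32-bit float
#' TIFF; acquisition metadata and the full 4-d array layout go to a JSON
#' sidecar holding the raw values, so `read_trial_stack()` round-trips the
#' stack exactly.
#'
#' @param stack A [trial_stack()].
#' @param path Base path; writes `<path>.tif` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trial_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  acq <- stack$acquisition
  avg <- apply(stack$data, c(2, 3, 4), mean)  # frames x rows x cols
  pages <- lapply(seq_len(dim(avg)[1]), function(f) avg[f, , ])
  rng <- range(unlist(pages))
  scaled <- lapply(pages, function(p)
    if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0)
  tiff::writeTIFF(scaled, paste0(path, ".tif"), bits.per.sample = 32L)
  meta <- list(condition_label = stack$condition_label,
               acquisition = unclass(acq),
               dim = dim(stack$data),
               tiff_range = rng,
               data = as.numeric(stack$data))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_stack
#' @export
read_trial_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  acq <- do.call(acquisition_config,
                 meta$acquisition[setdiff(names(meta$acquisition), "n_frames")])
  arr <- array(meta$data, dim = meta$dim)
  trial_stack(arr, acq, meta$condition_label)
}

#' Write session metadata as CSV
#'
#' One row per condition: label, type, position, size, luminance, current.
#'
#' @param session A [session_bundle()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_metadata <- function(session, path) {
  utils::write.csv(session$metadata, path, row.names = FALSE)
  invisible(path)
}

# Run `expr` under a deterministic RNG stream without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
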