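# Reduced acquisition geometries used throughout the tests: same 5 x 5 mm
# field and trial structure as the full recordings, coarser sampling so
# suites stay fast.

small_acq <- function(...) {
  args <- utils::modifyList(
    list(frame_rate = 10, trial_duration = 4, stim_onset = 0.5,
         image_rows = 40, image_cols = 40, pixel_pitch = 0.125,
         n_trials = 8),
    list(...))
  do.call(acquisition_config, args)
}

tiny_acq <- function(...) small_acq(image_rows = 30, image_cols = 30,
                                    n_trials = 4, ...)

# Near-noiseless level that keeps the z-score pipeline non-degenerate
# (frame-0 normalization needs non-zero pre-stimulus variance).
eps_noise <- 1e-4

default_cfg <- analysis_config()

preprocess_stack <- function(st, cfg = default_cfg)
  temporal_normalize(subtract_border_trend(st, cfg$border_width))

# Disc and ellipse masks for shape-descriptor tests.
disc_mask <- function(n, center, radius) {
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix((rc$r - center[1])^2 + (rc$c - center[2])^2 <= radius^2, n, n)
}

ellipse_mask <- function(n, center, a, b, orientation_deg) {
  th <- orientation_deg * pi / 180
  u <- c(-sin(th), cos(th)); v <- c(u[2], -u[1])
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  dr <- rc$r - center[1]; dc <- rc$c - center[2]
  pu <- dr * u[1] + dc * u[2]; pv <- dr * v[1] + dc * v[2]
  matrix((pu / a)^2 + (pv / b)^2 <= 1, n, n)
}

# Independent second-moment oracle: explicit sums + base eigen().
ellipse_oracle <- function(mask, pitch = 1) {
  idx <- which(mask, arr.ind = TRUE)
  mu <- colMeans(idx)
  dr <- idx[, 1] - mu[1]; dc <- idx[, 2] - mu[2]
  cov <- matrix(c(mean(dr^2) + 1 / 12, mean(dr * dc),
                  mean(dr * dc), mean(dc^2) + 1 / 12), 2, 2)
  e <- eigen(cov, symmetric = TRUE)
  list(major = 4 * sqrt(e$values[1]) * pitch,
       minor = 4 * sqrt(e$values[2]) * pitch,
       ar = sqrt(e$values[1] / e$values[2]),
       orientation = (atan2(-e$vectors[1, 1], e$vectors[2, 1]) *
                        180 / pi) %% 180,
       center = mu)
}

# Radially organized set with fixed positions and fresh orientation jitter.
rejitter <- function(set, od, jitter_sd, seed) {
  radial <- axial_angle(direction_angle(od[1] - set$centers[, 1],
                                        od[2] - set$centers[, 2]))
  withr::with_seed(seed,
    elongated_set(set$centers,
                  axial_angle(radial + stats::rnorm(nrow(set$centers),
                                                    sd = jitter_sd)),
                  com_offsets = set$com_offsets))
}
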