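# Preprocessing: from raw trial stacks to blank-normalized static z-score
# maps and DI/I maps, and thresholded activation regions.

#' Analysis configuration
#'
#' @param z_threshold Activation threshold in z units (negative; the
#'   initial dip is a negative signal).  Default -3.09.
#' @param smooth_kernel Side of the flat smoothing kernel in pixels (odd).
#'   Default 15.
#' @param static_window Two times in seconds after stimulus onset over
#'   which static maps are averaged.  Default 1.5 to 2.5 s.
#' @param border_width Width in pixels of the border ring used for the
#'   shared-artifact estimate.  Default 2.
#' @param blank_sd `"spatial"` (scalar sd across pixels of the blank
#'   static map, the default) or `"temporal"` (per-pixel sd across blank
#'   trial static maps).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(z_threshold = -3.09, smooth_kernel = 15,
                            static_window = c(1.5, 2.5), border_width = 2,
                            blank_sd = c("spatial", "temporal")) {
  stopifnot(z_threshold < 0, smooth_kernel %% 2 == 1,
            length(static_window) == 2, diff(static_window) > 0,
            border_width >= 1)
  blank_sd <- match.arg(blank_sd)
  structure(list(z_threshold = z_threshold, smooth_kernel = smooth_kernel,
                 static_window = static_window, border_width = border_width,
                 blank_sd = blank_sd),
            class = "analysis_config")
}

border_indices <- function(rows, cols, width) {
  rc <- expand_rc(rows, cols)
  which(rc$r <= width | rc$r > rows - width |
        rc$c <= width | rc$c > cols - width)
}

# Flatten one trial to frames x pixels and back.
trial_matrix <- function(stack, tr) {
  d <- dim(stack$data)
  matrix(stack$data[tr, , , ], d[2], d[3] * d[4])
}

#' Subtract the border-ring artifact time course
#'
#' Per trial, the spatial mean time course of the outer border ring
#' (artifact carrier outside the region of interest) is subtracted from
#' every pixel's time course, removing non-functional shared temporal
#' structure.  The subtracted course is centered on its temporal mean so
#' the operation removes the temporal pattern only and leaves the DC
#' level (an artifact-free stack passes through unchanged).
#'
#' @param stack A [trial_stack()].
#' @param border_width Ring width in pixels (> 0).
#' @return A [trial_stack()] with the trend removed.
#' @export
subtract_border_trend <- function(stack, border_width = 2) {
  if (border_width <= 0) stop("border_width must be positive")
  d <- dim(stack$data)
  if (d[3] <= 2 * border_width || d[4] <= 2 * border_width)
    stop("image too small for the requested border width")
  idx <- border_indices(d[3], d[4], border_width)
  out <- stack
  for (tr in seq_len(d[1])) {
    m <- trial_matrix(stack, tr)
    g <- rowMeans(m[, idx, drop = FALSE])
    g <- g - mean(g)
    out$data[tr, , , ] <- array(m - g, c(1, d[2], d[3], d[4]))
  }
  out
}

#' Temporal (frame-0) normalization
#'
#' Per trial and pixel, subtracts the mean and divides by the standard
#' deviation of the pre-stimulus window, so every pixel's pre-stimulus
#' time course has mean 0 and sd 1.  Pixels with zero pre-stimulus
#' variance are zeroed and flagged in the `"masked"` attribute.
#'
#' @param stack A [trial_stack()].
#' @return A normalized [trial_stack()] with a logical `"masked"`
#'   attribute (rows x cols).
#' @export
temporal_normalize <- function(stack) {
  acq <- stack$acquisition
  pre <- prestim_frames(acq)
  if (length(pre) < 2) stop("need at least 2 pre-stimulus frames")
  d <- dim(stack$data)
  masked <- matrix(FALSE, d[3], d[4])
  out <- stack
  for (tr in seq_len(d[1])) {
    m <- trial_matrix(stack, tr)
    mp <- m[pre, , drop = FALSE]
    mu <- colMeans(mp)
    v <- colSums(mp^2) - length(pre) * mu^2
    s <- sqrt(pmax(v, 0) / (length(pre) - 1))
    bad <- s <= 0
    masked <- masked | matrix(bad, d[3], d[4])
    s[bad] <- 1
    z <- sweep(sweep(m, 2, mu), 2, s, "/")
    z[, bad] <- 0
    out$data[tr, , , ] <- array(z, c(1, d[2], d[3], d[4]))
  }
  if (any(masked))
    warning(sum(masked), " pixel(s) with zero pre-stimulus variance masked")
  attr(out, "masked") <- masked
  out
}

static_window_frames <- function(acq, cfg) {
  t <- acq_times(acq) - acq$stim_onset
  which(t >= cfg$static_window[1] & t <= cfg$static_window[2])
}

# Trial- and window-averaged static map (rows x cols).
static_map <- function(stack, cfg) {
  win <- static_window_frames(stack$acquisition, cfg)
  if (length(win) == 0) stop("static window contains no frames")
  apply(stack$data[, win, , , drop = FALSE], c(3, 4), mean)
}

# Per-trial static maps, trials x rows x cols.
trial_static_maps <- function(stack, cfg) {
  win <- static_window_frames(stack$acquisition, cfg)
  apply(stack$data[, win, , , drop = FALSE], c(1, 3, 4), mean)
}

check_geometry <- function(a, b) {
  da <- dim(a$data); db <- dim(b$data)
  if (!all(da[c(2, 3, 4)] == db[c(2, 3, 4)]))
    stop("stimulated and blank stacks have mismatched geometry")
}

#' Z-score map container
#'
#' @param values rows x cols matrix of z values (negative = activation).
#' @param window The averaging window (s after stimulus onset).
#' @param blank_stats List with the blank mean map and the sd used.
#' @param pixel_pitch mm per pixel.
#' @return An object of class `zscore_map`.
#' @export
zscore_map <- function(values, window, blank_stats = NULL,
                       pixel_pitch = NA_real_) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(values = values, window = window,
                 blank_stats = blank_stats, pixel_pitch = pixel_pitch),
            class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  cat(sprintf("Z-score map %d x %d, window %.2f-%.2f s, min z = %.2f\n",
              nrow(x$values), ncol(x$values), x$window[1], x$window[2],
              min(x$values)))
  invisible(x)
}

#' @export
plot.zscore_map <- function(x, ...) {
  graphics::image(t(x$values)[, nrow(x$values):1],
                  col = grDevices::hcl.colors(64, "Blue-Red 3", rev = TRUE),
                  asp = nrow(x$values) / ncol(x$values), axes = FALSE, ...)
  invisible(x)
}

#' Blank-normalized static z-score map
#'
#' Averages the stimulated stack over trials and the static window, then
#' normalizes against the blank: pixel by pixel the blank static map is
#' subtracted and the result divided by the blank standard deviation over
#' space (or per-pixel across blank trials, see [analysis_config()]).
#' Both stacks are expected to be border-detrended and frame-0 normalized.
#'
#' @param stim,blank [trial_stack()]s of identical geometry.
#' @param cfg An [analysis_config()].
#' @return A [zscore_map()].
#' @export
compute_static_zscore_map <- function(stim, blank, cfg = analysis_config()) {
  check_geometry(stim, blank)
  s <- static_map(stim, cfg)
  b <- static_map(blank, cfg)
  if (cfg$blank_sd == "spatial") {
    sd_b <- stats::sd(as.vector(b))
  } else {
    tb <- trial_static_maps(blank, cfg)
    sd_b <- apply(tb, c(2, 3), stats::sd)
  }
  if (all(sd_b == 0)) {
    z <- s - b   # noiseless degenerate case: difference map in raw units
  } else {
    sd_b[sd_b == 0] <- min(sd_b[sd_b > 0])
    z <- (s - b) / sd_b
  }
  zscore_map(z, cfg$static_window,
             blank_stats = list(mean_map = b, sd = sd_b),
             pixel_pitch = stim$acquisition$pixel_pitch)
}

#' Fractional-change (DI/I) map
#'
#' Standard intrinsic-imaging normalization on raw stacks: each frame is
#' divided by the pixel's pre-stimulus mean, trial-averaged stimulated
#' frames are subtracted from blank frames frame-by-frame, and the result
#' is averaged over the static window.  Pixels with zero baseline are
#' zeroed and flagged in the `"masked"` attribute.
#'
#' @param stim,blank Raw (non-z-scored) [trial_stack()]s.
#' @param cfg An [analysis_config()].
#' @return rows x cols matrix of fractional change, class `dii_map`.
#' @export
compute_dii_map <- function(stim, blank, cfg = analysis_config()) {
  check_geometry(stim, blank)
  norm_frames <- function(stack) {
    acq <- stack$acquisition
    pre <- prestim_frames(acq)
    d <- dim(stack$data)
    acc <- matrix(0, d[2], d[3] * d[4])
    bad <- rep(FALSE, d[3] * d[4])
    for (tr in seq_len(d[1])) {
      m <- trial_matrix(stack, tr)
      base <- colMeans(m[pre, , drop = FALSE])
      zb <- base == 0
      bad <- bad | zb
      base[zb] <- 1
      acc <- acc + sweep(m, 2, base, "/")
    }
    list(m = acc / d[1], bad = bad)
  }
  s <- norm_frames(stim)
  b <- norm_frames(blank)
  diff <- s$m - b$m
  win <- static_window_frames(stim$acquisition, cfg)
  v <- colMeans(diff[win, , drop = FALSE])
  bad <- s$bad | b$bad
  v[bad] <- 0
  d <- dim(stim$data)
  out <- matrix(v, d[3], d[4])
  attr(out, "masked") <- matrix(bad, d[3], d[4])
  class(out) <- c("dii_map", class(out))
  out
}

# Renormalized flat (box) smoothing: each output pixel is the mean of the
# in-image pixels under a k x k window, so edges are not biased toward 0.
#' Flat-kernel smoothing with edge renormalization
#'
#' @param m Numeric matrix.
#' @param k Odd kernel side in pixels.
#' @return Smoothed matrix of the same size.
#' @export
smooth_flat <- function(m, k) {
  stopifnot(k %% 2 == 1, k >= 1)
  if (k == 1) return(m)
  boxsum(m, k) / boxsum(matrix(1, nrow(m), ncol(m)), k)
}

boxsum <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m); h <- (k - 1) / 2
  cs <- apply(m, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  p <- matrix(0, nr + 1, nc + 1)
  p[-1, -1] <- cs
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  p[r2 + 1, c2 + 1, drop = FALSE] - p[r1, c2 + 1, drop = FALSE] -
    p[r2 + 1, c1, drop = FALSE] + p[r1, c1, drop = FALSE]
}

#' Activation region container
#'
#' @param mask Logical matrix, the retained (largest) connected component.
#' @param labels Integer matrix labelling all suprathreshold components.
#' @param component_count Number of components found.
#' @param window Static window of the source map.
#' @param pixel_pitch mm per pixel.
#' @return An object of class `activation_region`; `is_empty()` tests for
#'   the explicit no-activation outcome.
#' @export
activation_region <- function(mask, labels = NULL, component_count = 0L,
                              window = NULL, pixel_pitch = NA_real_) {
  structure(list(mask = mask, labels = labels,
                 component_count = as.integer(component_count),
                 window = window, pixel_pitch = pixel_pitch,
                 n_pixels = sum(mask)),
            class = "activation_region")
}

#' @rdname activation_region
#' @param region An `activation_region`.
#' @export
is_empty <- function(region) region$n_pixels == 0

#' @export
print.activation_region <- function(x, ...) {
  if (is_empty(x)) cat("Activation region: empty (no suprathreshold pixels)\n")
  else cat(sprintf("Activation region: %d px (largest of %d component(s))\n",
                   x$n_pixels, x$component_count))
  invisible(x)
}

#' Extract the thresholded activation region
#'
#' Smooths the z map with a flat kernel, thresholds at
#' `cfg$z_threshold` (pixels at or below the threshold are active, the
#' dip being negative) and labels connected components
#' (8-connectivity).  The largest component is the activation; all
#' components are retained.  An empty region is a valid outcome, not an
#' error.
#'
#' @param zmap A [zscore_map()].
#' @param cfg An [analysis_config()].
#' @return An [activation_region()].
#' @export
extract_activation <- function(zmap, cfg = analysis_config()) {
  sm <- smooth_flat(zmap$values, cfg$smooth_kernel)
  bin <- sm <= cfg$z_threshold
  if (!any(bin))
    return(activation_region(bin, window = zmap$window,
                             pixel_pitch = zmap$pixel_pitch))
  labels <- EBImage::bwlabel(bin * 1)
  counts <- tabulate(labels[labels > 0])
  keep <- which.max(counts)
  activation_region(labels == keep, labels = labels,
                    component_count = length(counts),
                    window = zmap$window, pixel_pitch = zmap$pixel_pitch)
}
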