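# Two-source model of retinal activation under electrical stimulation:
# an isotropic flat-top Gaussian spread around the electrode plus an
# axons-en-passant "shadow cone" term, combined as IsoA + alpha * EP.
# The geometry lives on an N x N grid of retinal space with the optic
# disk and the electrode at configurable positions.

#' Retinal activation model configuration
#'
#' Defaults are the reference configuration: a 400 x 400 grid, optic disk
#' at (200, 100), electrode at (200, 150) (so the optic-disk-to-electrode
#' axis runs along +col), isotropic diffusion factor sigma = 1, electrode
#' radius S between 3 and 30 grid units, en-passant weight alpha up to 1.
#'
#' @param N Grid side in pixels.
#' @param electrode `(i0, j0)` electrode position.
#' @param optic_disk `(i_od, j_od)` optic-disk position.
#' @param S Electrode radius in grid units; must be smaller than the
#'   electrode-to-optic-disk distance.
#' @param sigma Isotropic diffusion factor (scales the Gaussian skirt to
#'   `sigma * S`).
#' @param alpha En-passant weight (>= 0).
#' @return An object of class `model_config`.
#' @export
model_config <- function(N = 400, electrode = c(200, 150),
                         optic_disk = c(200, 100), S = 5, sigma = 1,
                         alpha = 1) {
  stopifnot(N >= 10, length(electrode) == 2, length(optic_disk) == 2,
            S > 0, sigma > 0, alpha >= 0)
  if (any(electrode < 1 | electrode > N) || any(optic_disk < 1 | optic_disk > N))
    stop("electrode and optic disk must lie inside the grid")
  D <- sqrt(sum((electrode - optic_disk)^2))
  if (S >= D)
    stop("electrode radius S must be smaller than the electrode-to-optic-disk distance")
  structure(list(N = N, electrode = as.numeric(electrode),
                 optic_disk = as.numeric(optic_disk), S = S,
                 sigma = sigma, alpha = alpha, od_distance = D),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("Retinal activation model: N = %d, electrode (%g, %g), ",
                     "optic disk (%g, %g), S = %g, sigma = %g, alpha = %g\n"),
              x$N, x$electrode[1], x$electrode[2], x$optic_disk[1],
              x$optic_disk[2], x$S, x$sigma, x$alpha))
  invisible(x)
}

model_grid <- function(cfg) expand_rc(cfg$N, cfg$N)

#' Isotropic direct activation (flat-top Gaussian)
#'
#' Value 1 wherever the Euclidean distance to the electrode is below the
#' electrode radius `S`; beyond, `exp(-d^2 / (2 (sigma S)^2))`.  As
#' defined, the surface is discontinuous at `d = S` (dropping from 1 to
#' `exp(-1/2)` at sigma = 1); `continuous = TRUE` switches to the
#' continuous variant `exp(-(d - S)^2 / (2 (sigma S)^2))` outside the
#' electrode.
#'
#' @param cfg A [model_config()].
#' @param continuous Use the continuous skirt (default FALSE).
#' @return N x N matrix in `[0, 1]`.
#' @export
iso_activation <- function(cfg, continuous = FALSE) {
  g <- model_grid(cfg)
  d <- sqrt((g$r - cfg$electrode[1])^2 + (g$c - cfg$electrode[2])^2)
  sc <- 2 * (cfg$sigma * cfg$S)^2
  out <- if (continuous) exp(-(d - cfg$S)^2 / sc) else exp(-d^2 / sc)
  out[d < cfg$S] <- 1
  out
}

#' Axons-en-passant shadow-cone activation
#'
#' `EP = Att * Sig * Cone`:
#' * `Att = exp(-(d_elec - S)^2 / (2 N^2))`, a weak large-scale
#'   attenuation away from the electrode;
#' * `Sig`, a logistic gate of distance-to-optic-disk minus the
#'   electrode-to-optic-disk distance, slope scale `S/4` -- near 0 on the
#'   optic-disk side of the electrode eccentricity, near 1 beyond it
#'   (somata of axons passing over the electrode lie at larger
#'   eccentricities);
#' * `Cone = exp(-ConeAng^2 / (2 sigma^2))` on the half-plane beyond the
#'   optic disk along the electrode axis, with `ConeAng` the unsigned
#'   angle from the optic-disk-to-electrode axis normalized by the full
#'   cone angle `2 asin(S / D)` subtended by the electrode at the disk.
#'
#' @param cfg A [model_config()].
#' @return N x N matrix; the intermediate fields are attached as
#'   attributes `att`, `sig`, `cone`.
#' @export
en_passant_activation <- function(cfg) {
  g <- model_grid(cfg)
  e <- cfg$electrode; od <- cfg$optic_disk
  D <- cfg$od_distance
  d_elec <- sqrt((g$r - e[1])^2 + (g$c - e[2])^2)
  att <- exp(-(d_elec - cfg$S)^2 / (2 * cfg$N^2))
  d_od <- sqrt((g$r - od[1])^2 + (g$c - od[2])^2)
  sig <- 1 / (1 + exp(-(d_od - D) / (cfg$S / 4)))
  # unsigned angle at the optic disk between (pixel - od) and (electrode - od)
  ax <- (e - od) / D
  proj <- (g$r - od[1]) * ax[1] + (g$c - od[2]) * ax[2]
  perp <- (g$r - od[1]) * -ax[2] + (g$c - od[2]) * ax[1]
  ang <- abs(atan2(perp, proj))
  cone_full <- 2 * asin(cfg$S / D)
  cone <- exp(-(ang / cone_full)^2 / (2 * cfg$sigma^2))
  cone[proj <= 0] <- 0          # restrict to the far side of the disk
  cone[d_od == 0] <- 0
  ep <- att * sig * cone
  attr(ep, "att") <- att
  attr(ep, "sig") <- sig
  attr(ep, "cone") <- cone
  ep
}

#' Combine direct and en-passant activation
#'
#' Weighted sum `iso + alpha * ep`.
#'
#' @param iso,ep Matrices of identical size.
#' @param alpha En-passant weight.
#' @return Combined matrix.
#' @export
combine_activation <- function(iso, ep, alpha) {
  if (!all(dim(iso) == dim(ep))) stop("iso and ep must share geometry")
  ep <- matrix(as.numeric(ep), nrow(ep), ncol(ep))  # drop attached fields
  iso + alpha * ep
}

#' Full retinal activation map
#'
#' Builds the isotropic and en-passant fields and their weighted sum,
#' retaining the intermediate fields for inspection.
#'
#' @param cfg A [model_config()].
#' @param continuous_iso Passed to [iso_activation()].
#' @return An object of class `retinal_map` with fields `iso`, `ep`,
#'   `att`, `sig`, `cone`, `combined` and the `config`.
#' @export
retinal_activation_map <- function(cfg, continuous_iso = FALSE) {
  iso <- iso_activation(cfg, continuous_iso)
  ep <- en_passant_activation(cfg)
  combined <- combine_activation(iso, ep, cfg$alpha)
  structure(list(iso = iso,
                 ep = matrix(as.numeric(ep), cfg$N, cfg$N),
                 att = attr(ep, "att"), sig = attr(ep, "sig"),
                 cone = attr(ep, "cone"),
                 combined = combined, config = cfg),
            class = "retinal_map")
}

#' @export
print.retinal_map <- function(x, ...) {
  cat(sprintf("Retinal activation map %d x %d (S = %g, alpha = %g), max %.3f\n",
              x$config$N, x$config$N, x$config$S, x$config$alpha,
              max(x$combined)))
  invisible(x)
}

#' Shape metrics of a model activation map
#'
#' Thresholds the map at the half-maximum contour, keeps the connected
#' component containing the map maximum, and measures its extent along
#' the optic-disk-to-electrode axis (radial) and perpendicular to it
#' (tangential).  The aspect ratio is radial over tangential (may be
#' below 1).  `com_shift` is the vector from the region's geometric
#' center to its intensity-weighted center of mass.
#'
#' "Maximum" refers by default to the model's activation scale: both
#' component fields saturate at 1 (the flat top), so the half-maximum
#' contour sits at `contour_level * 1`.  Where the isotropic flat top
#' overlaps the rising en-passant gate the weighted sum exceeds that
#' scale (up to `1 + alpha`); `reference = "max"` instead thresholds at
#' a fraction of that observed map maximum, which hugs the overlap ridge
#' and suppresses the shadow-cone wedge from the contour.
#'
#' @param map A `retinal_map` or a plain matrix.
#' @param cfg The [model_config()] (taken from the map if omitted).
#' @param contour_level Contour fraction (default 0.5, half maximum).
#' @param reference `"scale"` (default; fraction of the unit component
#'   peak) or `"max"` (fraction of the observed map maximum).
#' @return An object of class `model_shape_metrics` with
#'   `aspect_ratio_radial`, `radial_extent`, `tangential_extent`,
#'   `extent` (equivalent diameter, grid units) and `com_shift`.
#' @export
model_shape_metrics <- function(map, cfg = NULL, contour_level = 0.5,
                                reference = c("scale", "max")) {
  reference <- match.arg(reference)
  if (inherits(map, "retinal_map")) {
    if (is.null(cfg)) cfg <- map$config
    m <- map$combined
  } else m <- map
  if (is.null(cfg)) stop("a model_config is required")
  thr <- contour_level * if (reference == "scale") 1 else max(m)
  bin <- m >= thr
  if (!any(bin)) stop("empty suprathreshold region")
  labels <- EBImage::bwlabel(bin * 1)
  peak <- which(m == max(m), arr.ind = TRUE)[1, ]
  keep <- labels[peak[1], peak[2]]
  if (keep == 0) keep <- which.max(tabulate(labels[labels > 0]))
  mask <- labels == keep
  idx <- which(mask, arr.ind = TRUE)
  ax <- (cfg$electrode - cfg$optic_disk) / cfg$od_distance
  proj_r <- (idx[, 1] - cfg$optic_disk[1]) * ax[1] +
    (idx[, 2] - cfg$optic_disk[2]) * ax[2]
  proj_t <- (idx[, 1] - cfg$optic_disk[1]) * -ax[2] +
    (idx[, 2] - cfg$optic_disk[2]) * ax[1]
  radial <- diff(range(proj_r)) + 1
  tangential <- diff(range(proj_t)) + 1
  gc <- colMeans(idx)
  w <- m[mask]
  com <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  structure(list(aspect_ratio_radial = radial / tangential,
                 radial_extent = radial, tangential_extent = tangential,
                 extent = 2 * sqrt(nrow(idx) / pi),
                 com_shift = com - gc,
                 geometric_center = gc, center_of_mass = com,
                 contour_level = contour_level, n_pixels = nrow(idx)),
            class = "model_shape_metrics")
}

#' @export
print.model_shape_metrics <- function(x, ...) {
  cat(sprintf(paste0("Model shape: AR (radial/tangential) = %.3f ",
                     "(%.1f / %.1f px), eq. diameter %.1f px\n"),
              x$aspect_ratio_radial, x$radial_extent, x$tangential_extent,
              x$extent))
  invisible(x)
}

#' Shadow-cone angle subtended by the stimulated surface
#'
#' The angle at the optic disk sustained by the active surface:
#' `2 * asin((z/2) / y)` in degrees, with the arcsine evaluated at the
#' actual stimulated active-surface radius `z/2`.  `linear = TRUE` gives
#' the linear-scaling alternative `2 * asin(x / y) * (z / (2 x))`.
#'
#' @param z Actual stimulated active-surface diameter, mm.
#' @param y Distance from the stimulation site to the optic disk, mm.
#' @param x MEA radius in mm (only used by the linear variant).
#' @param linear Use linear scaling of the MEA-radius angle.
#' @return Angle in degrees.
#' @export
shadow_cone_angle <- function(z, y, x = z / 2, linear = FALSE) {
  stopifnot(z > 0, y > 0)
  if (z / 2 > y) stop("active-surface radius exceeds the optic-disk distance")
  if (linear) {
    stopifnot(x > 0, x <= y)
    2 * asin(x / y) * 180 / pi * (z / (2 * x))
  } else {
    2 * asin((z / 2) / y) * 180 / pi
  }
}

#' Retino-cortical transform
#'
#' Integrates the local retino-cortical magnification
#' `RCM(R) = 1 / (a R + b)` (mm of cortex per degree at eccentricity R)
#' to map visual/retinal eccentricities to cortical distance:
#' `x(R) = (1/a) log((a R + b) / b)` per axis (limit `R / b` for a = 0).
#' Signed coordinates map as `sign(R) * x(|R|)`.
#'
#' @param points Matrix or data.frame with columns `(horizontal, vertical)`
#'   in degrees, or a numeric vector for one axis.
#' @param a_h,b_h Horizontal-axis constants (defaults 0.7, 30).
#' @param a_v,b_v Vertical-axis constants (defaults 0.4, 40).
#' @return Cortical positions in mm, same shape as `points`.
#' @export
retino_cortical_transform <- function(points, a_h = 0.7, b_h = 30,
                                      a_v = 0.4, b_v = 40) {
  stopifnot(b_h > 0, b_v > 0, a_h >= 0, a_v >= 0)
  axis_map <- function(R, a, b) {
    s <- sign(R); R <- abs(R)
    if (a == 0) s * R / b else s * log((a * R + b) / b) / a
  }
  if (is.null(dim(points))) return(axis_map(points, a_h, b_h))
  points <- as.matrix(points)
  cbind(axis_map(points[, 1], a_h, b_h), axis_map(points[, 2], a_v, b_v))
}

#' Local retino-cortical magnification
#'
#' @param R Eccentricity in degrees (>= 0).
#' @param a,b Constants of `RCM = 1 / (a R + b)`.
#' @return Magnification in mm/deg.
#' @export
rcm <- function(R, a = 0.7, b = 30) {
  stopifnot(all(R >= 0), b > 0, a >= 0)
  1 / (a * R + b)
}

#' Apply the retino-cortical transform to a model map
#'
#' Resamples a retinal-space activation map into cortical space: each
#' output (cortical mm) pixel is bilinearly sampled from the retinal map
#' at the eccentricity obtained by inverting the per-axis transform,
#' `R = b (exp(a x) - 1) / a`.  The origin (eccentricity 0 on both axes)
#' is the optic-disk position of `cfg`.
#'
#' @param map Matrix in retinal space (e.g. a `retinal_map$combined`).
#' @param cfg The [model_config()] providing the origin.
#' @param deg_per_px Degrees of visual angle per retinal grid pixel.
#' @param out_size Output side in pixels.
#' @param mm_per_px Output cortical sampling, mm per pixel; by default
#'   scaled so the transformed field of view fits.
#' @param ... Passed to [retino_cortical_transform()] (axis constants).
#' @return List with the cortical `map` (out_size x out_size), the
#'   origin pixel and `mm_per_px`.
#' @export
transform_model_map <- function(map, cfg, deg_per_px = 0.25,
                                out_size = nrow(map), mm_per_px = NULL,
                                ...) {
  n <- nrow(map)
  half_deg <- (n - 1) * deg_per_px
  max_mm <- retino_cortical_transform(cbind(half_deg, half_deg), ...)
  if (is.null(mm_per_px)) mm_per_px <- max(max_mm) / (out_size / 2)
  origin <- (out_size + 1) / 2
  xo <- (seq_len(out_size) - origin) * mm_per_px   # cortical mm per axis
  args <- list(...)
  a_h <- args$a_h %||% 0.7; b_h <- args$b_h %||% 30
  a_v <- args$a_v %||% 0.4; b_v <- args$b_v %||% 40
  inv <- function(x, a, b) {
    s <- sign(x); x <- abs(x)
    if (a == 0) s * x * b else s * b * (exp(a * x) - 1) / a
  }
  # vertical axis = rows, horizontal = cols
  R_r <- inv(xo, a_v, b_v) / deg_per_px + cfg$optic_disk[1]
  R_c <- inv(xo, a_h, b_h) / deg_per_px + cfg$optic_disk[2]
  out <- bilinear_sample(map, outer(R_r, rep(1, out_size)),
                         outer(rep(1, out_size), R_c))
  list(map = out, origin = c(origin, origin), mm_per_px = mm_per_px)
}

# Bilinear sampling of matrix m at fractional (row, col) coordinate
# matrices; out-of-range samples return 0.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * get(r0, c0) +
    (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) +
    fr * fc * get(r0 + 1, c0 + 1)
  matrix(v, nrow(r), ncol(r))
}

#' Sweep the model over electrode sizes and en-passant weights
#'
#' @param S_values Electrode radii to evaluate.
#' @param alpha_values En-passant weights.
#' @param cfg Base [model_config()] (S and alpha are overridden).
#' @param contour_level,reference Passed to [model_shape_metrics()].
#' @return `data.frame` with columns `S`, `alpha`, `cone_angle_deg`
#'   (full cone angle at the disk), `ar` and `extent`.
#' @export
model_ar_sweep <- function(S_values = c(3, 5, 7, 10, 20, 30),
                           alpha_values = 1, cfg = model_config(),
                           contour_level = 0.5,
                           reference = c("scale", "max")) {
  reference <- match.arg(reference)
  rows <- list()
  for (S in S_values) for (al in alpha_values) {
    ci <- model_config(cfg$N, cfg$electrode, cfg$optic_disk, S,
                       cfg$sigma, al)
    sm <- model_shape_metrics(retinal_activation_map(ci), ci, contour_level,
                              reference)
    rows[[length(rows) + 1]] <-
      data.frame(S = S, alpha = al,
                 cone_angle_deg = 2 * asin(S / ci$od_distance) * 180 / pi,
                 ar = sm$aspect_ratio_radial, extent = sm$extent)
  }
  do.call(rbind, rows)
}
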