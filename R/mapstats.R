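# Position, size and shape descriptors of activations; retinotopic polar
# maps; magnification and size-tuning fits.

#' |z|-weighted center of mass of an activation
#'
#' Computed on the (unsmoothed) z-scored map over the thresholded region.
#'
#' @param zmap A [zscore_map()].
#' @param region An [activation_region()].
#' @return Named numeric `(row, col)` in pixels, or `NULL` with a warning
#'   for an empty region (explicit no-activation result).
#' @export
center_of_mass <- function(zmap, region) {
  if (is_empty(region)) {
    warning("empty region: no activation center of mass")
    return(NULL)
  }
  idx <- which(region$mask, arr.ind = TRUE)
  w <- abs(zmap$values[region$mask])
  if (sum(w) == 0) w <- rep(1, length(w))
  c(row = sum(idx[, 1] * w) / sum(w), col = sum(idx[, 2] * w) / sum(w))
}

#' Equivalent ellipse of a binary region
#'
#' The ellipse with the same normalized second central moments as the
#' mask (each pixel treated as a unit square, hence the 1/12 variance
#' term): axis lengths are `4 * sqrt(eigenvalue)`, the equivalent
#' diameter is that of the circle of equal area, and the orientation is
#' the major-axis direction in degrees `[0, 180)` from +col,
#' counterclockwise on the displayed image.
#'
#' @param region An [activation_region()] (or logical matrix) with at
#'   least 3 pixels.
#' @param pixel_pitch mm per pixel (defaults to the region's own).
#' @return An object of class `equivalent_ellipse` with fields
#'   `geometric_center` (px), `major_axis_len`, `minor_axis_len`,
#'   `equivalent_diameter` (mm), `orientation` (deg) and `aspect_ratio`.
#' @export
equivalent_ellipse <- function(region, pixel_pitch = NULL) {
  if (inherits(region, "activation_region")) {
    if (is.null(pixel_pitch)) pixel_pitch <- region$pixel_pitch
    mask <- region$mask
  } else mask <- region
  if (is.null(pixel_pitch) || is.na(pixel_pitch)) pixel_pitch <- 1
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("region must contain at least 3 pixels")
  n <- nrow(idx)
  mu <- colMeans(idx)
  dr <- idx[, 1] - mu[1]; dc <- idx[, 2] - mu[2]
  # normalized central moments + 1/12 for the unit-square pixel footprint
  crr <- mean(dr^2) + 1 / 12
  ccc <- mean(dc^2) + 1 / 12
  crc <- mean(dr * dc)
  common <- sqrt((crr - ccc)^2 + 4 * crc^2)
  l1 <- (crr + ccc + common) / 2
  l2 <- (crr + ccc - common) / 2
  degenerate <- l2 < 1 / 12
  l2 <- max(l2, 1 / 12)   # minor-axis floor of one pixel for collinear sets
  # major-axis eigenvector of [[crr, crc], [crc, ccc]]
  if (common < .Machine$double.eps) {
    vec <- c(0, 1)   # isotropic: orientation conventionally 0
  } else if (abs(crc) > .Machine$double.eps) {
    vec <- c(l1 - ccc, crc)
  } else {
    vec <- if (crr >= ccc) c(1, 0) else c(0, 1)
  }
  orientation <- axial_angle(direction_angle(vec[1], vec[2]))
  structure(list(geometric_center = c(row = mu[[1]], col = mu[[2]]),
                 major_axis_len = 4 * sqrt(l1) * pixel_pitch,
                 minor_axis_len = 4 * sqrt(l2) * pixel_pitch,
                 equivalent_diameter = 2 * sqrt(n / pi) * pixel_pitch,
                 orientation = orientation,
                 aspect_ratio = sqrt(l1 / l2),
                 area_px = n, degenerate = degenerate,
                 pixel_pitch = pixel_pitch),
            class = "equivalent_ellipse")
}

#' @export
print.equivalent_ellipse <- function(x, ...) {
  cat(sprintf(paste0("Equivalent ellipse: center (%.1f, %.1f) px, ",
                     "axes %.3f x %.3f, eq. diameter %.3f, ",
                     "AR %.2f, orientation %.1f deg\n"),
              x$geometric_center[1], x$geometric_center[2],
              x$major_axis_len, x$minor_axis_len, x$equivalent_diameter,
              x$aspect_ratio, x$orientation))
  invisible(x)
}

#' Retinotopic polar maps
#'
#' Per pixel, the preferred azimuth and elevation are the
#' response-weighted centroids of the stimulus grid positions (responses
#' rectified to the activation sign, `max(0, -z)`); the strength is the
#' peak rectified response.  Pixels with no response anywhere are masked
#' (NA preference).
#'
#' @param zmaps List of [zscore_map()]s, one per grid position.
#' @param positions `data.frame` with `position_deg_x` (azimuth) and
#'   `position_deg_y` (elevation) per map.
#' @return An object of class `polar_maps` with matrices `azimuth_pref`,
#'   `elevation_pref`, `response_strength` and the grid `span`.
#' @export
build_polar_maps <- function(zmaps, positions) {
  stopifnot(length(zmaps) == nrow(positions))
  resp <- vapply(zmaps, function(z) pmax(0, -z$values),
                 matrix(0, nrow(zmaps[[1]]$values), ncol(zmaps[[1]]$values)))
  tot <- apply(resp, c(1, 2), sum)
  az <- apply(sweep(resp, 3, positions$position_deg_x, "*"), c(1, 2), sum)
  el <- apply(sweep(resp, 3, positions$position_deg_y, "*"), c(1, 2), sum)
  strength <- apply(resp, c(1, 2), max)
  masked <- tot == 0
  tot[masked] <- 1
  az <- az / tot; el <- el / tot
  az[masked] <- NA; el[masked] <- NA
  structure(list(azimuth_pref = az, elevation_pref = el,
                 response_strength = strength,
                 span = list(azimuth = range(positions$position_deg_x),
                             elevation = range(positions$position_deg_y)),
                 pixel_pitch = zmaps[[1]]$pixel_pitch),
            class = "polar_maps")
}

#' @export
print.polar_maps <- function(x, ...) {
  cat(sprintf("Polar maps %d x %d px, azimuth span [%g, %g], elevation [%g, %g]\n",
              nrow(x$azimuth_pref), ncol(x$azimuth_pref),
              x$span$azimuth[1], x$span$azimuth[2],
              x$span$elevation[1], x$span$elevation[2]))
  invisible(x)
}

#' Expected cortical position of a visual-field location
#'
#' The intersection of the two cardinal polar maps: the responsive pixel
#' whose (azimuth, elevation) preference is closest to the queried
#' visual position.
#'
#' @param pm A [polar_maps()].
#' @param visual_pos `(azimuth, elevation)` in degrees, inside the mapped
#'   span.
#' @param min_strength Pixels with strength below this fraction of the
#'   maximum are ignored.
#' @return Named numeric `(row, col)` in pixels.
#' @export
expected_cortical_position <- function(pm, visual_pos, min_strength = 0.05) {
  if (visual_pos[1] < pm$span$azimuth[1] ||
      visual_pos[1] > pm$span$azimuth[2] ||
      visual_pos[2] < pm$span$elevation[1] ||
      visual_pos[2] > pm$span$elevation[2])
    stop("visual position lies outside the mapped span")
  ok <- !is.na(pm$azimuth_pref) &
    pm$response_strength >= min_strength * max(pm$response_strength)
  if (!any(ok)) stop("no responsive pixels in the polar maps")
  d2 <- (pm$azimuth_pref - visual_pos[1])^2 +
    (pm$elevation_pref - visual_pos[2])^2
  d2[!ok] <- Inf
  idx <- which(d2 == min(d2), arr.ind = TRUE)
  # tie-break: among equally close preferences, take the strongest pixel
  if (nrow(idx) > 1)
    idx <- idx[which.max(pm$response_strength[idx]), , drop = FALSE]
  c(row = idx[1, 1], col = idx[1, 2])
}

#' Positional error between expected and observed centers
#'
#' @param expected,com `(row, col)` positions in mm.
#' @param magnification Cortical magnification in mm/deg (> 0).
#' @return An object of class `position_metrics` with `error_mm` and the
#'   degree-equivalent `error_deg_eq = error_mm / magnification`.
#' @export
positional_error <- function(expected, com, magnification) {
  if (magnification <= 0) stop("magnification must be positive")
  err <- sqrt(sum((expected - com)^2))
  structure(list(expected_position = expected, center_of_mass = com,
                 error_mm = err, error_deg_eq = err / magnification,
                 magnification = magnification),
            class = "position_metrics")
}

#' @export
print.position_metrics <- function(x, ...) {
  cat(sprintf("Positional error: %.3f mm (%.2f deg-eq at %.3f mm/deg)\n",
              x$error_mm, x$error_deg_eq, x$magnification))
  invisible(x)
}

#' Convert visual-field distance to cortical distance (and back)
#'
#' Linear conversion by the cortical magnification factor.
#'
#' @param deg Visual distance in degrees.
#' @param magnification mm/deg.
#' @return Cortical distance in mm (`deg_to_mm`) or degrees (`mm_to_deg`).
#' @export
deg_to_mm <- function(deg, magnification) {
  stopifnot(magnification > 0)
  deg * magnification
}

#' @rdname deg_to_mm
#' @param mm Cortical distance in mm.
#' @export
mm_to_deg <- function(mm, magnification) {
  stopifnot(magnification > 0)
  mm / magnification
}

#' Fit the cortical magnification factor
#'
#' Least-squares slope of cortical distance (mm) against visual distance
#' (degrees), with or without an intercept.
#'
#' @param visual_deg,cortical_mm Paired distances.
#' @param intercept Include an intercept term (default TRUE).
#' @return List with `slope` (mm/deg), `intercept`, `r_squared` and the
#'   underlying `lm` fit.
#' @export
fit_magnification <- function(visual_deg, cortical_mm, intercept = TRUE) {
  stopifnot(length(visual_deg) == length(cortical_mm))
  if (length(unique(visual_deg)) < 2)
    stop("need at least 2 distinct visual distances")
  fit <- if (intercept) stats::lm(cortical_mm ~ visual_deg)
         else stats::lm(cortical_mm ~ visual_deg + 0)
  co <- stats::coef(fit)
  list(slope = unname(co[["visual_deg"]]),
       intercept = if (intercept) unname(co[[1]]) else 0,
       r_squared = suppressWarnings(summary(fit)$r.squared),
       fit = fit)
}

#' Fit the size-tuning function and invert it
#'
#' Linear fit of cortical activation extent (mm) against visual stimulus
#' size (degrees); `equivalent_visual_size()` inverts the fitted line to
#' express a cortical extent as the visual size that would have evoked
#' it.
#'
#' @param sizes_deg,extents_mm Paired observations.
#' @return Object of class `size_tuning_fit` with `slope` (mm/deg),
#'   `intercept` (mm) and the `lm` fit.
#' @export
fit_size_tuning <- function(sizes_deg, extents_mm) {
  stopifnot(length(sizes_deg) == length(extents_mm))
  if (length(unique(sizes_deg)) < 2)
    stop("need at least 2 distinct sizes")
  fit <- stats::lm(extents_mm ~ sizes_deg)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[["sizes_deg"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 data_span = range(sizes_deg), fit = fit),
            class = "size_tuning_fit")
}

#' @rdname fit_size_tuning
#' @param fit A `size_tuning_fit`.
#' @param extent_mm Cortical extent(s) to invert.
#' @return Equivalent visual size(s) in degrees; values implying sizes
#'   beyond twice the fitted span are flagged with a warning and an
#'   `"extrapolated"` attribute.
#' @export
equivalent_visual_size <- function(fit, extent_mm) {
  stopifnot(inherits(fit, "size_tuning_fit"))
  size <- (extent_mm - fit$intercept) / fit$slope
  extrap <- size > 2 * fit$data_span[2] | size < fit$data_span[1] / 2
  if (any(extrap))
    warning("equivalent size extrapolates beyond twice the fitted span")
  attr(size, "extrapolated") <- extrap
  size
}

#' Per-condition metrics table
#'
#' Convenience reducer: preprocesses each condition of a session
#' (border-detrend, frame-0 normalize, blank z-score), extracts the
#' activation, and tabulates position/size/shape metrics in mm.
#'
#' @param session A [session_bundle()].
#' @param cfg An [analysis_config()].
#' @return `data.frame`, one row per condition: `label`, `com_row_mm`,
#'   `com_col_mm`, `extent_mm`, `ar`, `orientation_deg`, `amplitude_z`
#'   (peak negative z), `n_pixels`, `empty`.
#' @export
measure_session <- function(session, cfg = analysis_config()) {
  pre <- function(st) temporal_normalize(
    subtract_border_trend(st, cfg$border_width))
  blank <- pre(session$blank)
  pitch <- session$blank$acquisition$pixel_pitch
  rows <- lapply(seq_along(session$stacks), function(k) {
    st <- session$stacks[[k]]
    z <- compute_static_zscore_map(pre(st), blank, cfg)
    reg <- extract_activation(z, cfg)
    if (is_empty(reg))
      return(data.frame(label = st$condition_label, com_row_mm = NA,
                        com_col_mm = NA, extent_mm = NA, ar = NA,
                        orientation_deg = NA, amplitude_z = min(z$values),
                        n_pixels = 0L, empty = TRUE))
    com <- center_of_mass(z, reg)
    ell <- equivalent_ellipse(reg, pitch)
    data.frame(label = st$condition_label,
               com_row_mm = com[["row"]] * pitch,
               com_col_mm = com[["col"]] * pitch,
               extent_mm = ell$equivalent_diameter,
               ar = ell$aspect_ratio,
               orientation_deg = ell$orientation,
               amplitude_z = min(z$values),
               n_pixels = reg$n_pixels, empty = FALSE)
  })
  do.call(rbind, rows)
}
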