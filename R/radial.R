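# Radial-organization statistics: how well elongated activations point
# toward a common center (the optic-disk representation), the optimal
# such center, a Monte-Carlo null for the arrangement, and alignment /
# averaging of maps along the radial axis.

# Axial angles (deg) of the directions from each site to each candidate:
# candidates x sites matrix.
site_candidate_angles <- function(centers, candidates) {
  dr <- outer(candidates[, 1], centers[, 1], "-")
  dc <- outer(candidates[, 2], centers[, 2], "-")
  axial_angle(atan2(-dr, dc) * 180 / pi)
}

row_medians <- function(m) {
  n <- nrow(m); k <- ncol(m)
  ms <- matrix(m[order(row(m), m)], n, k, byrow = TRUE)
  if (k %% 2 == 1) ms[, (k + 1) / 2]
  else (ms[, k / 2] + ms[, k / 2 + 1]) / 2
}

#' Median angular deviation from a radial arrangement
#'
#' For each site, the axial difference (in `[0, 90]`) between the site's
#' orientation and the direction from the site to the candidate center;
#' the median over sites is returned.  Sites coincident with the
#' candidate are skipped with a warning.
#'
#' @param set An [elongated_set()].
#' @param candidate `(row, col)` candidate center, same units as the set.
#' @return Median deviation in degrees, with per-site deviations in the
#'   `"per_site"` attribute.
#' @export
median_angular_deviation <- function(set, candidate) {
  dr <- candidate[1] - set$centers[, 1]
  dc <- candidate[2] - set$centers[, 2]
  coincident <- dr == 0 & dc == 0
  if (any(coincident))
    warning(sum(coincident), " site(s) coincident with the candidate skipped")
  radial <- axial_angle(direction_angle(dr, dc))
  dev <- axial_difference(set$orientations, radial)
  dev[coincident] <- NA
  out <- stats::median(dev, na.rm = TRUE)
  attr(out, "per_site") <- dev
  out
}

default_search_grid <- function(set, resolution = 0.1, pad = 1) {
  r <- range(set$centers[, 1]); c <- range(set$centers[, 2])
  list(rows = seq(r[1] - pad, r[2] + pad, by = resolution),
       cols = seq(c[1] - pad, c[2] + pad, by = resolution))
}

#' Optimal radial center of an elongated activation set
#'
#' Exhaustive grid search for the position minimizing
#' [median_angular_deviation()]; ties are broken deterministically by the
#' first candidate in row-major order.
#'
#' @param set An [elongated_set()].
#' @param search_grid List with numeric `rows` and `cols` vectors of
#'   candidate coordinates; default covers the sites' bounding box padded
#'   by 1 unit at 0.1-unit resolution.
#' @return An object of class `radial_fit` with `optimal_center`,
#'   `median_deviation` and `per_site_deviation`.
#' @export
optimize_radial_center <- function(set, search_grid = NULL) {
  if (is.null(search_grid)) search_grid <- default_search_grid(set)
  stopifnot(length(search_grid$rows) >= 1, length(search_grid$cols) >= 1)
  cand <- as.matrix(expand.grid(col = search_grid$cols,
                                row = search_grid$rows))[, c("row", "col")]
  a <- site_candidate_angles(set$centers, cand)
  dev <- axial_fold_matrix(a, set$orientations)
  med <- row_medians(dev)
  best <- which.min(med)
  center <- c(row = cand[best, "row"], col = cand[best, "col"])
  structure(list(optimal_center = center,
                 median_deviation = med[best],
                 per_site_deviation = dev[best, ],
                 search_grid = search_grid),
            class = "radial_fit")
}

# |fold into [0,90]| of (angles - orientations) row-wise.
axial_fold_matrix <- function(a, orientations) {
  d <- abs(sweep(a, 2, orientations) %% 180)
  pmin(d, 180 - d)
}

#' @export
print.radial_fit <- function(x, ...) {
  cat(sprintf("Radial fit: optimal center (%.2f, %.2f), median deviation %.1f deg\n",
              x$optimal_center[1], x$optimal_center[2], x$median_deviation))
  invisible(x)
}

#' Monte-Carlo null for the radial-organization statistic
#'
#' Replaces the observed orientations with i.i.d. uniform axial angles,
#' re-optimizes the radial center for each draw, and records the
#' minimized median deviation -- the distribution of the statistic
#' expected by chance at the observed positions.
#'
#' @param set An [elongated_set()] (positions are kept).
#' @param n_iter Number of random draws (>= 100; default 1000).
#' @param seed Integer seed.
#' @param search_grid As in [optimize_radial_center()].
#' @return An object of class `monte_carlo_null` with `null_deviations`,
#'   `mean`, `sd`, `n_iter` and `seed`.
#' @export
monte_carlo_null <- function(set, n_iter = 1000, seed = 1,
                             search_grid = NULL) {
  if (n_iter < 100) stop("n_iter must be at least 100")
  if (is.null(search_grid)) search_grid <- default_search_grid(set)
  cand <- as.matrix(expand.grid(col = search_grid$cols,
                                row = search_grid$rows))[, c("row", "col")]
  a <- site_candidate_angles(set$centers, cand)
  ns <- nrow(set$centers)
  nulls <- numeric(n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      orient <- stats::runif(ns, 0, 180)
      nulls[i] <- min(row_medians(axial_fold_matrix(a, orient)))
    }
  })
  structure(list(null_deviations = nulls, mean = mean(nulls),
                 sd = stats::sd(nulls), n_iter = n_iter, seed = seed),
            class = "monte_carlo_null")
}

#' @export
print.monte_carlo_null <- function(x, ...) {
  cat(sprintf("Monte-Carlo null (%d iter): mean %.1f deg, sd %.1f deg\n",
              x$n_iter, x$mean, x$sd))
  invisible(x)
}

#' P-values for an observed radial deviation against the null
#'
#' `p_empirical` is the fraction of null draws at or below the observed
#' deviation (area under the curve to the left); `p_gaussian` is the
#' lower Gaussian tail given the null mean and sd, with
#' `z = (mean - observed) / sd`.
#'
#' @param null A [monte_carlo_null()], or any list with `mean` and `sd`
#'   (printed summary statistics are enough for the Gaussian p).
#' @param observed Observed median angular deviation in degrees.
#' @return List with `p_empirical` (NA when only summary statistics are
#'   given), `p_gaussian` and `z`.
#' @export
gaussian_p <- function(null, observed) {
  mu <- null[["mean"]]; s <- null[["sd"]]
  if (is.null(mu) || is.null(s)) stop("null must provide mean and sd")
  if (s == 0) stop("null sd is zero")
  p_emp <- if (!is.null(null[["null_deviations"]]))
    mean(null[["null_deviations"]] <= observed) else NA_real_
  list(p_empirical = p_emp,
       p_gaussian = stats::pnorm(observed, mean = mu, sd = s),
       z = (mu - observed) / s)
}

#' Center-of-mass deviation relative to the radial center
#'
#' Expresses each site's center-of-mass offset (center-of-mass minus
#' geometric center) as a signed angle in a frame whose 0-degree axis
#' points from the site toward the radial center; +/-180 degrees means a
#' displacement directly away from it.  Sites with zero-length offsets
#' are skipped.
#'
#' @param set An [elongated_set()] with `com_offsets`.
#' @param radial_center `(row, col)` radial center.
#' @return List with `per_site` signed angles (degrees, `(-180, 180]`)
#'   and their `circular_mean`.
#' @export
com_deviation_analysis <- function(set, radial_center) {
  if (is.null(set$com_offsets)) stop("set has no com_offsets")
  len <- sqrt(rowSums(set$com_offsets^2))
  keep <- len > 0
  if (!all(keep)) warning(sum(!keep), " zero-length offset(s) skipped")
  off_ang <- direction_angle(set$com_offsets[keep, 1],
                             set$com_offsets[keep, 2])
  toward <- direction_angle(radial_center[1] - set$centers[keep, 1],
                            radial_center[2] - set$centers[keep, 2])
  rel <- ((off_ang - toward + 180) %% 360) - 180
  rel[rel == -180] <- 180
  th <- rel * pi / 180
  circ <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
  list(per_site = rel, circular_mean = circ)
}

#' Rotate a map about a point (bilinear)
#'
#' Rotates the image content counterclockwise (on the displayed image)
#' by `angle` degrees about `center_in`, placing that point at
#' `center_out` of an `out_dim` canvas.  Out-of-field samples are 0.
#'
#' @param m Numeric matrix.
#' @param angle Rotation in degrees.
#' @param center_in `(row, col)` pivot in `m` (default: matrix center).
#' @param out_dim Output `(rows, cols)` (default: `dim(m)`).
#' @param center_out `(row, col)` of the pivot in the output.
#' @return Rotated matrix.
#' @export
rotate_map <- function(m, angle, center_in = (dim(m) + 1) / 2,
                       out_dim = dim(m), center_out = (out_dim + 1) / 2) {
  psi <- -angle * pi / 180      # inverse mapping rotates the other way
  o_r <- matrix(seq_len(out_dim[1]) - center_out[1], out_dim[1], out_dim[2])
  o_c <- matrix(seq_len(out_dim[2]) - center_out[2], out_dim[1], out_dim[2],
                byrow = TRUE)
  ox <- o_c; oy <- -o_r         # display coords: x right, y up
  sx <- cos(psi) * ox - sin(psi) * oy
  sy <- sin(psi) * ox + cos(psi) * oy
  bilinear_sample(m, center_in[1] - sy, center_in[2] + sx)
}

#' Align maps along their radial axes and average them
#'
#' Each map is translated so its activation center sits at the canvas
#' center and rotated so its radial axis (direction toward the radial
#' center) points right (+col); the aligned maps are averaged pixel-wise.
#' A secondary contour at z = `contour_z` of the average is reported.
#'
#' @param maps List (>= 2) of [zscore_map()]s or matrices of identical
#'   dimensions.
#' @param centers n x 2 matrix of `(row, col)` activation centers, px.
#' @param radial_axes Directional angles (degrees) from each center
#'   toward the radial center.
#' @param out_dim Output canvas `(rows, cols)`; defaults to the input
#'   dimensions.
#' @param contour_z Secondary contour level (default -4.5).
#' @return An object of class `aligned_average` with the `average`
#'   matrix, the secondary `contour` mask and `n_maps`.
#' @export
align_and_average_maps <- function(maps, centers, radial_axes,
                                   out_dim = NULL, contour_z = -4.5) {
  if (length(maps) < 2) stop("need at least 2 maps")
  mats <- lapply(maps, function(m) if (inherits(m, "zscore_map")) m$values else m)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), TRUE)))
    stop("maps have mismatched geometry")
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == length(maps),
            length(radial_axes) == length(maps))
  if (is.null(out_dim)) out_dim <- d
  acc <- matrix(0, out_dim[1], out_dim[2])
  for (k in seq_along(mats)) {
    acc <- acc + rotate_map(mats[[k]], -radial_axes[k],
                            center_in = centers[k, ], out_dim = out_dim)
  }
  avg <- acc / length(mats)
  structure(list(average = avg, contour = avg <= contour_z,
                 contour_z = contour_z, n_maps = length(mats)),
            class = "aligned_average")
}

#' @export
print.aligned_average <- function(x, ...) {
  cat(sprintf("Aligned average of %d maps, min %.2f, %d px below z = %g\n",
              x$n_maps, min(x$average), sum(x$contour), x$contour_z))
  invisible(x)
}
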