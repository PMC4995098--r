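# Angle conventions shared across the package.
#
# Image coordinates are (row, col), 1-based, row increasing downward.
# A direction (drow, dcol) has angle atan2(-drow, dcol) in degrees, i.e.
# 0 deg points along +col and angles increase counterclockwise on the
# displayed image.  Axial quantities (ellipse orientations) live in
# [0, 180); axial differences are folded into [0, 90].

#' Direction angle of a displacement
#'
#' @param drow,dcol Displacement components (row increases downward).
#' @return Angle in degrees in `(-180, 180]`; 0 along +col, counterclockwise
#'   positive on the displayed image.
#' @export
direction_angle <- function(drow, dcol) atan2(-drow, dcol) * 180 / pi

#' Fold an angle to the axial range \[0, 180)
#'
#' @param angle Angle(s) in degrees.
#' @return Angle(s) modulo 180.
#' @export
axial_angle <- function(angle) angle %% 180

#' Axial difference between two orientations
#'
#' Smallest angle between two undirected axes, in `[0, 90]`.
#'
#' @param a,b Orientations in degrees (any range; treated modulo 180).
#' @return Difference(s) in degrees in `[0, 90]`.
#' @export
axial_difference <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

# Unit vector (drow, dcol) of an axial orientation in degrees.
axis_vector <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(-sin(th), cos(th))
}
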