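## Circular (headless, 180-degree periodic) angle utilities.
##
## Fibre orientations carry no arrow: theta and theta + 180 denote the same
## direction. All planar angles in the package live in [0, 180) degrees,
## measured from the +x axis with y pointing down (image convention), so a
## positive angle appears clockwise on screen.

#' Headless angular distance
#'
#' Distance between two planar orientations identified with their opposites,
#' i.e. `min(|a-b| mod 180, 180 - |a-b| mod 180)`.
#'
#' @param a,b angles in degrees (any real values); recycled.
#' @return distances in degrees, in `[0, 90]`.
#' @export
ang_dist180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' @rdname ang_dist180
#' @details `ang_norm180()` maps angles to the canonical range `[0, 180)`.
#' @param x angles in degrees.
#' @export
ang_norm180 <- function(x) x %% 180

## Circular distance on the full circle (360-periodic), degrees.
ang_dist360 <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of headless angles
#'
#' Mean direction via the double-angle resultant: angles are doubled, averaged
#' as unit vectors, and halved back. Returns `NA` when the resultant length is
#' numerically zero (no preferred direction).
#'
#' @param x angles in degrees.
#' @return mean angle in `[0, 180)`, or `NA_real_`.
#' @export
circ_mean180 <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  s <- mean(sinpi(x / 90))  # sin(2x deg)
  c <- mean(cospi(x / 90))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  ang_norm180(atan2(s, c) * 90 / pi)
}

#' Circular median of headless angles
#'
#' The data angle minimising the summed headless distance
#' `sum_i min(|t - x_i|, 180 - |t - x_i|)`; ties are broken by the smaller
#' canonical angle. With data `{0, 170, 10}` the median is 0 (170 is 10 degrees
#' from 0 on the headless circle).
#'
#' @param x angles in degrees.
#' @return median angle in `[0, 180)`.
#' @export
circ_median180 <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  cand <- sort(unique(ang_norm180(x)))
  cost <- vapply(cand, function(t) sum(ang_dist180(t, x)), numeric(1))
  cand[which.min(cost)]  # which.min takes the first (smallest angle) on ties
}

#' Circular interquartile range of headless angles
#'
#' The data are rotated so that the circular median maps to 90 degrees, then
#' the ordinary interquartile range of the rotated values (in `[0, 180)`) is
#' taken. Used by the regional classifier's direction-reliability test.
#'
#' @param x angles in degrees.
#' @return IQR in degrees.
#' @export
circ_iqr180 <- function(x) {
  if (length(x) < 2L) return(0)
  med <- circ_median180(x)
  r <- ang_norm180(x - med + 90)
  unname(diff(stats::quantile(r, c(0.25, 0.75))))
}

#' Circular (Frechet) variance of headless angles, in squared degrees
#'
#' Minimum over mean directions mu of the mean squared headless deviation
#' `mean(d(x_i, mu)^2)`. For a 50/50 two-point distribution 90 degrees apart
#' this equals (45 deg)^2 = 2025. The minimiser is located by a half-degree
#' grid refined around the best cell.
#'
#' @param x angles in degrees.
#' @return variance in deg^2.
#' @export
circ_var180 <- function(x) {
  if (length(x) < 2L) return(0)
  cost <- function(mu) vapply(mu, function(m) mean(ang_dist180(m, x)^2), numeric(1))
  grid <- seq(0, 179.5, by = 0.5)
  c0 <- cost(grid)
  b <- grid[which.min(c0)]
  fine <- seq(b - 0.5, b + 0.5, by = 0.01)
  min(cost(fine))
}

## Spherical helpers: headless unit 3-vectors <-> (theta planar deg, phi
## elevation deg), with v = (cos th cos ph, sin th cos ph, sin ph).
sph_to_vec <- function(theta, phi) {
  t <- theta * pi / 180; p <- phi * pi / 180
  cbind(cos(t) * cos(p), sin(t) * cos(p), sin(p))
}

vec_to_sph <- function(v) {
  phi <- asin(pmin(1, pmax(-1, v[3]))) * 180 / pi
  theta <- (atan2(v[2], v[1]) * 180 / pi) %% 360
  c(theta = theta, phi = phi)
}

#' Headless angle between two unit 3-vectors, degrees
#' @param u,v unit 3-vectors.
#' @return angle in `[0, 90]` degrees.
#' @export
vec_angle_headless <- function(u, v) {
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}
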