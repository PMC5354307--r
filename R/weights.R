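## Weighting stage: voxel weighting = stereologically corrected nuclear density
## times nuclear-direction homogeneity.
##
## A nucleus inclined out of the cut plane is intersected by more section
## planes than one lying flat: with major/minor axis fractions rM/l and rm/l
## of the voxel length, the per-plane observation probability is
## approximately max(rM sin phi, rm) / l, so the in-plane mean count Np
## under-represents flat-lying nuclei. Inverting gives
## N = min(Np l / (rM dz), Np l / rm) with dz the |z-component| of the voxel
## direction.

#' Stereological density weight
#'
#' @param Np mean in-plane (cross-sectional) nuclear count of the voxel.
#' @param dz absolute z-component of the voxel direction, in `[0, 1]`.
#' @param rM_over_l,rm_over_l nucleus major/minor axis over voxel length.
#' @param N0,N1 lower saturation and upper cut of the weight ramp.
#' @return list with `N` (inferred voxel count) and `w_d` in `[0, 1]`.
#'   Vectorised over `Np` / `dz`.
#' @export
density_weight <- function(Np, dz, rM_over_l = 0.3, rm_over_l = 0.1,
                           N0 = 10, N1 = 160) {
  stopifnot(all(Np >= 0), all(dz >= -1e-9 & dz <= 1 + 1e-9))
  N <- pmin(Np / (rM_over_l * pmax(dz, 0)), Np / rm_over_l)
  N[!is.finite(N)] <- (Np / rm_over_l)[!is.finite(N)]
  w <- ifelse(N <= N0, N / N0, ifelse(N > N1, 0, 1))
  list(N = N, w_d = w)
}

#' Nuclear-direction homogeneity weight
#'
#' Squared mean resultant length of the per-nucleus direction vectors
#' `v(theta, phi) = (sin phi cos 2theta, sin phi sin 2theta, cos phi)` where
#' `theta` are the nuclear planar angles (doubled so headless directions
#' average correctly) and `phi` is the voxel's *co-latitude* (angle from the
#' z-axis, so `cos phi` equals the direction's z-component). Aligned nuclei
#' give 1; in-plane perpendicular pairs give 0; a vertical voxel's planar
#' scatter is discounted by `sin^2 phi`.
#'
#' @param S nuclear planar angles in the voxel, deg.
#' @param phi_colat voxel angle from the z-axis, deg.
#' @return `w_h` in `[0, 1]` (0 for an empty set).
#' @export
homogeneity_weight <- function(S, phi_colat) {
  n <- length(S)
  if (n == 0L) return(0)
  sp <- sin(phi_colat * pi / 180); cp <- cos(phi_colat * pi / 180)
  v <- cbind(sp * cospi(S / 90), sp * sinpi(S / 90), rep(cp, n))
  sum(colSums(v)^2) / n^2
}

## Homogeneity from the per-voxel sufficient statistics (sum cos 2theta,
## sum sin 2theta, count): |sum v|^2 / n^2 expands to
## (sin^2 phi (C^2 + S^2) + n^2 cos^2 phi) / n^2.
homogeneity_from_sums <- function(sum_cos2, sum_sin2, n, phi_colat) {
  sp2 <- sin(phi_colat * pi / 180)^2
  cp2 <- cos(phi_colat * pi / 180)^2
  out <- (sp2 * (sum_cos2^2 + sum_sin2^2) + n^2 * cp2) / pmax(n, 1)^2
  out[n == 0] <- 0
  out
}

#' Compute voxel weights for an assigned direction volume
#'
#' `weight = w_d * w_h` per voxel: stereologically corrected density ramp
#' times nuclear-direction homogeneity (computed from the pooled registered
#' nuclear angles via their per-voxel circular sufficient statistics, with
#' the inferred elevation converted to the co-latitude the homogeneity vector
#' needs).
#'
#' @param vol assigned volume (from [assign_directions()]).
#' @param cfg a [pipeline_config()].
#' @return the volume with `weight`, `w_d`, `w_h` and `N_inferred` arrays.
#' @export
voxel_weights <- function(vol, cfg = pipeline_config()) {
  d <- dim(vol$category)
  dz <- abs(vol$vec[, , , 3])
  dw <- density_weight(vol$count, dz, cfg$rM_over_l, cfg$rm_over_l, cfg$N0, cfg$N1)
  phi_colat <- acos(pmin(1, dz)) * 180 / pi
  ## the angle sums span the whole pooled substack, so the matching multiset
  ## size is the pooled nucleus count, not the per-section mean
  n_ang <- vol$n_angles %||% vol$count
  wh <- homogeneity_from_sums(vol$sum_cos2, vol$sum_sin2, n_ang, phi_colat)
  w <- dw$w_d * wh
  w[vol$category == CAT_EMPTY] <- 0
  vol$w_d <- array(dw$w_d, d); vol$w_d[vol$category == CAT_EMPTY] <- 0
  vol$w_h <- array(wh, d)
  vol$N_inferred <- array(dw$N, d)
  vol$weight <- array(w, d)
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
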