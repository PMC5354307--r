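## Direction-inference stage: R interface to the boundary-distance direction inference.

#' Distance to the inferred bundle boundary along a direction
#'
#' Walks the discretised line through voxel `p` in direction `v` (both arms
#' simultaneously, consecutive points in adjacent voxels) applying the
#' temporary-vector rule and the 30-degree same-bundle criteria; returns the
#' stopping index, capped at `L_max`. Leaving the volume counts as a
#' boundary. An isolated voxel returns 1; an empty voxel returns 0.
#'
#' @param vol a volume skeleton (from [assemble_stack()]) or assigned volume;
#'   needs `category`, `theta`, and (optionally) `vec`/`assigned`.
#' @param p voxel coordinate, 0-based `c(x, y, z)`.
#' @param v direction vector (non-zero).
#' @param L_max cap on the step count.
#' @return integer step count.
#' @export
line_length <- function(vol, p, v, L_max = 40L) {
  if (sqrt(sum(v^2)) < 1e-12) stop("direction vector must be non-zero")
  v <- v / sqrt(sum(v^2))
  d <- dim(vol$category)
  n <- prod(d)
  if (!is.null(vol$vec) && !is.null(vol$assigned)) {
    vx <- as.numeric(vol$vec[, , , 1]); vy <- as.numeric(vol$vec[, , , 2])
    vz <- as.numeric(vol$vec[, , , 3])
    assigned <- as.integer(vol$assigned)
  } else {
    vx <- vy <- vz <- numeric(n)
    assigned <- integer(n)
  }
  cpp_line_length(as.integer(vol$category), as.numeric(vol$theta),
                  vx, vy, vz, assigned, as.integer(d),
                  as.integer(p), as.numeric(v), as.integer(L_max))
}

#' Assign full 3-D headless directions to all non-empty voxels
#'
#' Planar voxels first (elevation from the length-weighted candidate average
#' over -60..60 degrees in 15-degree steps, processed in descending
#' boundary-contrast order), then vertical voxels (azimuth grid of 32
#' candidates at 11.25 degrees, elevation restricted to 30..90 degrees).
#' Assigned voxels participate immediately in later probes.
#'
#' @param vol a volume skeleton from [assemble_stack()] (or a phantom with
#'   `category` / `theta` arrays).
#' @param cfg a [pipeline_config()] (uses `L_max`).
#' @return the volume with `vec` (nx x ny x nz x 3 unit vectors), `assigned`,
#'   `order_score`, and `lowconf` arrays added.
#' @export
assign_directions <- function(vol, cfg = pipeline_config()) {
  d <- dim(vol$category)
  r <- cpp_assign_directions(as.integer(vol$category), as.numeric(vol$theta),
                             as.integer(d), as.integer(cfg$L_max))
  vec <- array(0, c(d, 3))
  vec[, , , 1] <- r$vx; vec[, , , 2] <- r$vy; vec[, , , 3] <- r$vz
  vol$vec <- vec
  vol$assigned <- array(r$assigned, d)
  vol$order_score <- array(r$score, d)
  vol$lowconf <- array(r$lowconf, d)
  vol
}

#' Per-voxel headless angular error against a ground-truth field
#' @param vol assigned volume (with `vec`).
#' @param truth_vec nx x ny x nz x 3 ground-truth unit vectors.
#' @return array of great-circle headless errors in degrees (`NA` where
#'   unassigned).
#' @export
direction_errors <- function(vol, truth_vec) {
  d <- dim(vol$category)
  dot <- vol$vec[, , , 1] * truth_vec[, , , 1] +
    vol$vec[, , , 2] * truth_vec[, , , 2] +
    vol$vec[, , , 3] * truth_vec[, , , 3]
  err <- acos(pmin(1, abs(dot))) * 180 / pi
  err[vol$assigned == 0] <- NA_real_
  err
}
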