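## Masking stage: suppressing non-myometrial tissue.
##
## Vasculature is located through red blood cells: RBC-sized objects
## (< 14 um^2) escape the smooth-muscle size filter but are recorded, and
## voxels where they dominate the detected objects mark vessel interiors.
## Placental tissue is located through its high all-size nuclear density
## (>= 4500 / mm^2) with hysteresis thresholding of the smoothed binary map.

## 26-connected 3-D labelling via iterative label propagation (minimum
## neighbour label until fixpoint). Volumes here are small.
label26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    nb <- array(Inf, d)
    labi <- lab
    labi[!mask] <- Inf
    for (r in seq_len(nrow(offs))) {
      s <- shift_arr3(labi, offs[r, 1], offs[r, 2], offs[r, 3])
      s[s == 0] <- Inf
      nb <- pmin(nb, s)
    }
    new <- pmin(labi, nb)
    new[!mask] <- 0
    new[!is.finite(new)] <- 0
    if (all(new == lab)) break
    lab <- new
  }
  out <- array(0L, d)
  out[mask] <- match(lab[mask], sort(unique(lab[mask])))
  out
}

dilate1_26 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (dx || dy || dz) out <- out | shift_arr3(mask, dx, dy, dz) > 0
  out
}

#' Vessel mask from red-blood-cell density
#'
#' Per-voxel fraction of detected objects that are RBC-sized, Gaussian
#' smoothed (variance 1), thresholded, 26-connected clusters of at least 9
#' voxels kept, then dilated by one voxel to include the vessel wall.
#'
#' @param vol volume with `count_small` and `count_all` arrays.
#' @param cfg a [pipeline_config()].
#' @return logical vessel mask.
#' @export
detect_vessels <- function(vol, cfg = pipeline_config()) {
  frac <- ifelse(vol$count_all > 0, vol$count_small / vol$count_all, 0)
  if (!any(frac > 0)) return(array(FALSE, dim(frac)))
  sm <- gauss_smooth(frac, sqrt(cfg$vessel_var))
  bin <- sm >= cfg$vessel_frac_min
  if (!any(bin)) return(bin)
  lab <- label26(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= cfg$vessel_min_voxels)
  core <- array(lab %in% keep & lab > 0, dim(lab))
  dilate1_26(core)
}

#' Placenta mask from extended nuclear density
#'
#' All-size nuclear density (nuclei per mm^2 of section area) thresholded at
#' the minimum density, smoothed with a sigma = 4 voxel Gaussian, hysteresis
#' thresholded (connected sets everywhere >= 0.3 containing a point >= 0.6),
#' and clusters of at least 10000 voxels kept.
#'
#' @param vol volume with `count_all` (per-section mean counts) and
#'   `pitch_um`.
#' @param cfg a [pipeline_config()].
#' @return logical placenta mask.
#' @export
detect_placenta <- function(vol, cfg = pipeline_config()) {
  area_mm2 <- (vol$pitch_um / 1000)^2
  density <- vol$count_all / area_mm2
  bin <- (density >= cfg$placenta_density_min) * 1
  if (!any(bin > 0)) return(array(FALSE, dim(bin)))
  sm <- gauss_smooth(bin, cfg$placenta_sigma)
  lo <- sm >= cfg$placenta_lo
  if (!any(lo)) return(array(FALSE, dim(bin)))
  lab <- label26(lo)
  hi_labels <- unique(lab[sm >= cfg$placenta_hi & lab > 0])
  sizes <- tabulate(lab[lab > 0])
  keep <- intersect(hi_labels, which(sizes >= cfg$placenta_min_voxels))
  array(lab %in% keep & lab > 0, dim(lab))
}
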