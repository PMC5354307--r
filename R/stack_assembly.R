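## Assembly stage: uniformly spaced representative slides.
##
## Sections are 5 um thick but region pixels are ~47.5 um wide, so the
## registered, gap-ridden stack is condensed into substacks one voxel thick:
## range z holds slide numbers s with z*lr/ls <= s < (z+1)*lr/ls. Pooling
## nuclei across a substack and re-running the regional classifier yields one
## representative slide per range with average cross-sectional counts, making
## the final grid (nearly) isotropic.

#' Partition surviving slide numbers into one-voxel-thick ranges
#'
#' A range with a single surviving slide is extended by the nearest surviving
#' slide outside it; an empty range borrows the nearest surviving slide on
#' each side. Equidistant neighbours resolve to the lower slide number.
#'
#' @param slide_numbers integer vector of surviving slide numbers.
#' @param l_r region (voxel) pitch, um.
#' @param l_s section thickness, um.
#' @return data.frame with `z` and list-column `slides` (the substack for
#'   each z).
#' @export
partition_ranges <- function(slide_numbers, l_r = 47.488, l_s = 5) {
  stopifnot(l_r > l_s, l_s > 0)
  if (!length(slide_numbers)) stop("empty stack")
  s <- sort(unique(slide_numbers))
  ratio <- l_r / l_s
  zs <- seq.int(floor(min(s) / ratio), floor(max(s) / ratio))
  nearest <- function(cands, lo, hi) {
    ## nearest surviving slide to the range [lo, hi); ties -> lower number
    d <- pmax(lo - cands, cands - (hi - 1e-9), 0)
    cands[order(d, cands)][1]
  }
  res <- lapply(zs, function(z) {
    lo <- z * ratio; hi <- (z + 1) * ratio
    inside <- s[s >= lo & s < hi]
    if (length(inside) >= 2L) return(inside)
    if (length(inside) == 1L) {
      outside <- setdiff(s, inside)
      if (!length(outside)) return(inside)
      return(sort(c(inside, nearest(outside, lo, hi))))
    }
    left <- s[s < lo]; right <- s[s >= hi]
    sort(c(if (length(left)) max(left), if (length(right)) min(right)))
  })
  keep <- lengths(res) > 0L
  data.frame(z = zs[keep], slides = I(res[keep]))
}

#' Build a representative slide from a substack
#'
#' Nuclei from all substack slides are pooled per region footprint and
#' re-classified exactly as in the regional classifier; counts become average
#' cross-sectional counts (pooled total divided by the number of source
#' slides).
#'
#' @param ellipses_list list of warped nucleus tables (with `rx`, `ry` region
#'   coordinates, `area_um2`, `aspect`, `theta`).
#' @param template a [regional_slide()] supplying the frame.
#' @param cfg a [pipeline_config()].
#' @param z_index z position of the representative slide.
#' @return a [regional_slide()] with fractional counts and
#'   `source_slides` attribute.
#' @export
build_representative <- function(ellipses_list, template, cfg = pipeline_config(),
                                 z_index = 0L) {
  nsl <- length(ellipses_list)
  stopifnot(nsl >= 1L)
  pooled <- do.call(rbind, ellipses_list)
  rs <- regrid_regional(pooled, template, cfg)
  rs$n_angles <- rs$count          # pooled multiset size for the angle sums
  rs$count <- rs$count / nsl
  rs$count_all <- rs$count_all / nsl
  rs$count_small <- rs$count_small / nsl
  rs$slide_number <- as.integer(z_index)
  attr(rs, "source_slides") <- nsl
  rs
}

#' Assemble a registered stack into a direction volume skeleton
#'
#' Runs [partition_ranges()] and [build_representative()] over the stack and
#' stacks the representative slides into 3-D arrays ready for the 3-D
#' direction inference.
#'
#' @param ellipses per-slide warped nucleus tables (region coordinates).
#' @param slides per-slide [regional_slide()] objects (frames must agree).
#' @param slide_numbers surviving slide numbers (same order as lists).
#' @param cfg a [pipeline_config()].
#' @param crop logical: trim empty border region-pixels (with a 1-voxel
#'   margin) to keep the volume compact.
#' @return a `direction_volume` list: `category`, `theta`, `count`,
#'   `count_all`, `count_small`, `sum_cos2`, `sum_sin2` (nx x ny x nz arrays),
#'   `pitch_um`, `z_index`, `sources`.
#' @export
assemble_stack <- function(ellipses, slides, slide_numbers, cfg = pipeline_config(),
                           crop = TRUE) {
  pr <- partition_ranges(slide_numbers, cfg$resolution$region_um, cfg$slice_um)
  template <- slides[[1]]
  reps <- lapply(seq_len(nrow(pr)), function(k) {
    ids <- match(pr$slides[[k]], slide_numbers)
    build_representative(ellipses[ids], template, cfg, z_index = pr$z[k])
  })
  d <- dim(template$category); nz <- length(reps)
  arr <- function(field, init) {
    a <- array(init, c(d, nz))
    for (k in seq_len(nz)) a[, , k] <- reps[[k]][[field]]
    a
  }
  vol <- list(category = arr("category", CAT_EMPTY), theta = arr("theta", NA_real_),
              count = arr("count", 0), count_all = arr("count_all", 0),
              count_small = arr("count_small", 0),
              sum_cos2 = arr("sum_cos2", 0), sum_sin2 = arr("sum_sin2", 0),
              n_angles = arr("n_angles", 0),
              pitch_um = template$um_per_pixel, z_index = pr$z,
              sources = lapply(pr$slides, identity))
  if (crop) vol <- crop_volume(vol)
  structure(vol, class = "direction_volume_skeleton")
}

crop_volume <- function(vol) {
  occ <- vol$category != CAT_EMPTY
  if (!any(occ)) return(vol)
  ix <- range(which(apply(occ, 1, any))); iy <- range(which(apply(occ, 2, any)))
  ix <- c(max(1, ix[1] - 1), min(dim(occ)[1], ix[2] + 1))
  iy <- c(max(1, iy[1] - 1), min(dim(occ)[2], iy[2] + 1))
  for (f in c("category", "theta", "count", "count_all", "count_small",
              "sum_cos2", "sum_sin2", "n_angles"))
    vol[[f]] <- vol[[f]][ix[1]:ix[2], iy[1]:iy[2], , drop = FALSE]
  vol
}
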