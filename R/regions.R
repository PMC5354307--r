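## Coarse-graining stage: coarse-graining nuclear orientation into regional direction maps.
##
## Each 128 x 128 px region becomes one "region pixel" carrying a category
## (planar / vertical / empty), a nuclear count, and - for planar pixels - a
## headless direction. Slides are padded to a fixed frame so registration
## cannot push tissue out of bounds.

CAT_EMPTY <- 0L
CAT_PLANAR <- 1L
CAT_VERTICAL <- 2L

#' Construct a regional slide
#'
#' Grids are `frame_w x frame_h` matrices indexed `[x, y]` (x = column of the
#' padded frame, 1-based internally; exported coordinates are 0-based).
#'
#' @param category integer matrix (0 empty, 1 planar, 2 vertical).
#' @param theta numeric matrix of planar angles, deg in `[0, 180)`, `NA` where
#'   not planar.
#' @param count numeric matrix, smooth-muscle-sized nuclei per region (may be
#'   fractional for representative slides).
#' @param count_all,count_small all-size and sub-RBC-size nucleus counts.
#' @param slide_number integer z coordinate (section numbering, gaps encode
#'   discarded sections).
#' @param um_per_pixel region pitch in um.
#' @param sum_cos2,sum_sin2 per-region sums of cos/sin of doubled nuclear
#'   angles (sufficient statistics for the homogeneity weighting).
#' @param n_angles size of the nuclear-angle multiset behind
#'   `sum_cos2`/`sum_sin2` (defaults to `count`; differs for representative
#'   slides where `count` is a per-section mean).
#' @return a `regional_slide` list.
#' @export
regional_slide <- function(category, theta = NULL, count = NULL, count_all = NULL,
                           count_small = NULL, slide_number = 0L,
                           um_per_pixel = 47.488,
                           sum_cos2 = NULL, sum_sin2 = NULL, n_angles = NULL) {
  d <- dim(category)
  zero <- matrix(0, d[1], d[2])
  if (is.null(theta)) { theta <- zero * NA_real_ }
  if (is.null(count)) { count <- zero + (category != CAT_EMPTY) * 2 }
  if (is.null(count_all)) count_all <- count
  if (is.null(count_small)) count_small <- zero
  if (is.null(sum_cos2)) sum_cos2 <- zero
  if (is.null(sum_sin2)) sum_sin2 <- zero
  if (is.null(n_angles)) n_angles <- count
  structure(list(category = category, theta = theta, count = count,
                 count_all = count_all, count_small = count_small,
                 sum_cos2 = sum_cos2, sum_sin2 = sum_sin2, n_angles = n_angles,
                 slide_number = as.integer(slide_number),
                 um_per_pixel = um_per_pixel),
            class = "regional_slide")
}

#' @export
print.regional_slide <- function(x, ...) {
  d <- dim(x$category)
  cat(sprintf("regional_slide %d: %d x %d region px (%.1f um pitch), %d non-empty\n",
              x$slide_number, d[1], d[2], x$um_per_pixel, sum(x$category != CAT_EMPTY)))
  invisible(x)
}

#' Classify the nuclei of one region
#'
#' Ellipses are first restricted to the smooth-muscle size band (10-60 um^2).
#' Fewer than two such nuclei make the region *empty*. Nuclei with aspect
#' ratio > 2.0 are planar-class, < 1.6 vertical-class, and indeterminate
#' nuclei (aspect in `[1.6, 2.0]`) count in both classes. If the
#' vertical-class fraction exceeds 5/9 the region is *vertical*; otherwise it
#' is *planar* with direction equal to the circular median of the nuclear
#' angles - unless the circular interquartile range of those angles exceeds
#' 45 degrees, in which case the direction is deemed unreliable and the region
#' is reclassified *vertical*.
#'
#' @param ellipses ellipse data.frame (see [fit_ellipses()]); rows of any size.
#' @param cfg a [pipeline_config()].
#' @return list with `category`, `theta` (`NA` unless planar), `count`,
#'   `count_all`, `count_small`, `sum_cos2`, `sum_sin2`.
#' @export
classify_region <- function(ellipses, cfg = pipeline_config()) {
  sm <- ellipses[ellipses$area_um2 >= cfg$sm_area_um2[1] &
                   ellipses$area_um2 <= cfg$sm_area_um2[2], , drop = FALSE]
  out <- list(category = CAT_EMPTY, theta = NA_real_, count = nrow(sm),
              count_all = nrow(ellipses),
              count_small = sum(ellipses$area_um2 < cfg$rbc_max_um2),
              sum_cos2 = sum(cospi(sm$theta / 90)),
              sum_sin2 = sum(sinpi(sm$theta / 90)))
  if (nrow(sm) < 2L) return(out)
  n_planar <- sum(sm$aspect > cfg$aspect_planar)
  n_vert <- sum(sm$aspect < cfg$aspect_vertical)
  n_ind <- nrow(sm) - n_planar - n_vert
  if ((n_vert + n_ind) / (n_planar + n_vert + 2 * n_ind) > cfg$vertical_fraction) {
    out$category <- CAT_VERTICAL
    return(out)
  }
  th <- circ_median180(sm$theta)
  if (circ_iqr180(sm$theta) > cfg$iqr_max_deg) {
    out$category <- CAT_VERTICAL
  } else {
    out$category <- CAT_PLANAR
    out$theta <- th
  }
  out
}

#' Grid a slide's ellipses into a padded regional frame
#'
#' Each ellipse is assigned to the 128 x 128 px region containing its centre
#' (floor division of global pixel coordinates). The occupied content is
#' centred in the fixed `frame_w x frame_h` frame, padded with empty regions.
#'
#' @param ellipses ellipse data.frame with global px coordinates.
#' @param cfg a [pipeline_config()].
#' @param slide_number slide z index.
#' @param content_px optional `c(width, height)` of the scanned slide in px,
#'   used for centring; defaults to the ellipse bounding box.
#' @return a [regional_slide()].
#' @export
pad_and_grid <- function(ellipses, cfg = pipeline_config(), slide_number = 0L,
                         content_px = NULL) {
  res <- cfg$resolution
  W <- res$frame_w; H <- res$frame_h; rp <- res$region_px
  cat <- matrix(CAT_EMPTY, W, H)
  theta <- matrix(NA_real_, W, H)
  count <- matrix(0, W, H); count_all <- matrix(0, W, H); count_small <- matrix(0, W, H)
  sc2 <- matrix(0, W, H); ss2 <- matrix(0, W, H)
  offset_regions <- c(0, 0)
  if (nrow(ellipses)) {
    rx <- floor(ellipses$cx / rp)
    ry <- floor(ellipses$cy / rp)
    if (is.null(content_px)) {
      x0 <- min(rx); y0 <- min(ry)
      nwx <- max(rx) - x0 + 1L; nwy <- max(ry) - y0 + 1L
    } else {
      x0 <- 0L; y0 <- 0L
      nwx <- ceiling(content_px[1] / rp); nwy <- ceiling(content_px[2] / rp)
    }
    if (nwx > W || nwy > H) stop("frame overflow: content larger than the padded frame")
    offx <- floor((W - nwx) / 2); offy <- floor((H - nwy) / 2)
    offset_regions <- c(offx - x0, offy - y0)
    gx <- rx - x0 + offx + 1L  # 1-based frame indices
    gy <- ry - y0 + offy + 1L
    ok <- gx >= 1L & gx <= W & gy >= 1L & gy <= H
    key <- (gx - 1L) + W * (gy - 1L)
    for (k in split(which(ok), key[ok])) {
      e <- ellipses[k, , drop = FALSE]
      cl <- classify_region(e, cfg)
      i <- gx[k[1]]; j <- gy[k[1]]
      cat[i, j] <- cl$category; theta[i, j] <- cl$theta
      count[i, j] <- cl$count; count_all[i, j] <- cl$count_all
      count_small[i, j] <- cl$count_small
      sc2[i, j] <- cl$sum_cos2; ss2[i, j] <- cl$sum_sin2
    }
  }
  out <- regional_slide(cat, theta, count, count_all, count_small,
                        slide_number, um_per_pixel = res$region_um,
                        sum_cos2 = sc2, sum_sin2 = ss2)
  attr(out, "offset_regions") <- offset_regions
  out
}

#' Write / read a regional slide as a 3-plane 16-bit TIFF plus JSON sidecar
#'
#' Planes are (category, theta x 10, count); the sidecar records the slide
#' number and region pitch.
#' @param slide a [regional_slide()].
#' @param path output TIFF path (sidecar gets extension `.json`).
#' @return `path`, invisibly (`read_regional_slide` returns the slide).
#' @export
write_regional_slide <- function(slide, path) {
  d <- dim(slide$category)
  th <- slide$theta; th[is.na(th)] <- 0
  a <- array(0, c(d[2], d[1], 3))  # rows = y for TIFF
  a[, , 1] <- t(slide$category) / 65535
  a[, , 2] <- t(round(th * 10)) / 65535
  a[, , 3] <- t(round(slide$count)) / 65535
  tiff::writeTIFF(a, path, bits.per.sample = 16L)
  jsonlite::write_json(list(slide_number = slide$slide_number,
                            um_per_pixel = slide$um_per_pixel),
                       sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regional_slide
#' @export
read_regional_slide <- function(path) {
  a <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path))
  cat <- t(round(a[, , 1] * 65535)); mode(cat) <- "integer"
  theta <- t(round(a[, , 2] * 65535)) / 10
  theta[cat != CAT_PLANAR] <- NA_real_
  count <- t(round(a[, , 3] * 65535))
  regional_slide(cat, theta, count, slide_number = meta$slide_number,
                 um_per_pixel = meta$um_per_pixel)
}
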