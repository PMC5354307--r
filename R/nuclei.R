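## Extraction stage: nuclear ellipse extraction from RGB tiles.
##
## H&E colours nuclei purple and surrounding tissue pink, so nuclei have both
## lower red and lower blue than their local surroundings. Thresholds are
## local (per 32 x 32 px window) because staining intensity varies across and
## within slides.

#' Local colour thresholding of an H&E tile
#'
#' A pixel is foreground (nucleus) iff its red value is below 5/6 of its
#' window's mean red AND its blue value is below the window's mean blue.
#' Windows tile the image without overlap; partial windows at the borders use
#' their own mean.
#'
#' @param tile RGB image array, `dim = c(rows, cols, 3)`, numeric
#'   (any common scale: thresholds are ratios of local means).
#' @param cfg a [resolution_config()].
#' @param red_factor,blue_factor threshold scale factors (defaults 5/6 and 1).
#' @return logical matrix `rows x cols`, `TRUE` = nucleus pixel.
#' @export
local_threshold <- function(tile, cfg = resolution_config(),
                            red_factor = 5 / 6, blue_factor = 1) {
  if (length(dim(tile)) != 3L || dim(tile)[3] < 3L)
    stop("tile must be an RGB image array (rows x cols x 3)")
  r <- tile[, , 1]; b <- tile[, , 3]
  w <- cfg$window_px
  (r < red_factor * block_mean_expand(r, w)) & (b < blue_factor * block_mean_expand(b, w))
}

## 8-connected labelling: EBImage::bwlabel is 4-connected; merge labels that
## touch diagonally with a union-find pass.
label8 <- function(mask) {
  lbl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lbl)
  if (n < 2L) return(lbl)
  pairs <- rbind(
    cbind(as.vector(lbl[-nrow(lbl), -ncol(lbl)]), as.vector(lbl[-1, -1])),
    cbind(as.vector(lbl[-nrow(lbl), -1]), as.vector(lbl[-1, -ncol(lbl)])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lbl
  out[lbl > 0] <- relab[lbl[lbl > 0]]
  out
}

#' Fit second-moment ellipses to a binary nucleus mask
#'
#' Connected components (8-connectivity) are fitted by their second-moment
#' ellipse: the major axis follows the component's principal direction, the
#' aspect ratio comes from the moment eigenvalues, and the axes are scaled so
#' the ellipse area equals the component pixel area (the particle-analysis
#' convention). Components outside the 40-600 px area band are retained in
#' the table but flagged non-primary: smaller objects (red blood cells,
#' debris) and larger clusters feed the tissue-masking stages.
#'
#' @param mask logical matrix from [local_threshold()].
#' @param cfg a [resolution_config()].
#' @param offset_px `c(x, y)` tile offset in global 0-based pixels.
#' @param min_area_px,max_area_px primary size filter (px).
#' @return data.frame with columns `cx, cy` (global px, 0-based, x rightward,
#'   y downward), `area_px`, `area_um2`, `aspect` (>= 1), `theta` (deg in
#'   `[0, 180)`, major axis from +x), `primary` (logical),
#'   `size_class` (`"noise"`, `"primary"`, `"cluster"`).
#' @export
fit_ellipses <- function(mask, cfg = resolution_config(), offset_px = c(0, 0),
                         min_area_px = 40, max_area_px = 600) {
  empty <- data.frame(cx = numeric(0), cy = numeric(0), area_px = numeric(0),
                      area_um2 = numeric(0), aspect = numeric(0), theta = numeric(0),
                      primary = logical(0), size_class = character(0))
  if (!any(mask)) return(empty)
  lbl <- label8(mask)
  idx <- which(lbl > 0, arr.ind = TRUE)
  g <- lbl[lbl > 0]
  x <- idx[, 2] - 1  # column -> x
  y <- idx[, 1] - 1  # row    -> y
  n <- as.vector(rowsum(rep(1, length(g)), g))
  sx <- as.vector(rowsum(x, g)); sy <- as.vector(rowsum(y, g))
  sxx <- as.vector(rowsum(x^2, g)); syy <- as.vector(rowsum(y^2, g))
  sxy <- as.vector(rowsum(x * y, g))
  cx <- sx / n; cy <- sy / n
  ## central second moments; +1/12 treats each pixel as a unit square
  mxx <- sxx / n - cx^2 + 1 / 12
  myy <- syy / n - cy^2 + 1 / 12
  mxy <- sxy / n - cx * cy
  tr <- mxx + myy
  det <- mxx * myy - mxy^2
  disc <- sqrt(pmax(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- pmax(tr / 2 - disc, 1e-9)
  aspect <- sqrt(l1 / l2)
  theta <- ang_norm180(0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi)
  size_class <- ifelse(n < min_area_px, "noise",
                       ifelse(n > max_area_px, "cluster", "primary"))
  data.frame(cx = cx + offset_px[1], cy = cy + offset_px[2],
             area_px = n, area_um2 = n * cfg$um_per_px_x * cfg$um_per_px_y,
             aspect = aspect, theta = theta,
             primary = size_class == "primary", size_class = size_class)
}

#' Extract nuclear ellipses from one RGB tile
#'
#' Convenience wrapper: [local_threshold()] then [fit_ellipses()].
#' @inheritParams local_threshold
#' @inheritParams fit_ellipses
#' @return ellipse data.frame (see [fit_ellipses()]).
#' @export
extract_nuclei <- function(tile, cfg = resolution_config(), offset_px = c(0, 0)) {
  fit_ellipses(local_threshold(tile, cfg), cfg, offset_px)
}

#' Read a TIFF tile and extract nuclei
#' @param path TIFF file path.
#' @param tile_index `c(i, j)` 0-based tile grid index; the global offset is
#'   `tile_index * tile size`.
#' @inheritParams local_threshold
#' @return ellipse data.frame.
#' @export
extract_nuclei_tiff <- function(path, cfg = resolution_config(), tile_index = c(0, 0)) {
  img <- tiff::readTIFF(path)
  extract_nuclei(img, cfg, offset_px = c(tile_index[1] * dim(img)[2],
                                         tile_index[2] * dim(img)[1]))
}
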