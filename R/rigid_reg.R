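## Rigid-registration stage: whole-slide alignment by alternating translation /
## rotation generalised Hough optimisation on Canny edges of the
## nuclear-count image.
##
## The shape registered is the tissue edge: region counts scaled by 20 make a
## grey image, Canny (Gaussian sd 3 px, Sobel radius 1, hysteresis 50/30)
## extracts its boundary, and integer accumulators over translations and
## polar-angle shifts find the transform maximising edge coincidence.

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding. Written for the regional count images; thresholds
#' apply to the Sobel gradient magnitude of the smoothed 0-255 grey image.
#'
#' @param grey numeric matrix (indexed `[x, y]`).
#' @param sigma Gaussian sd in px.
#' @param hi,lo hysteresis thresholds.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(grey, sigma = 3, hi = 50, lo = 30) {
  g <- gauss_smooth(grey, sigma)
  ## Sobel radius 1, x = dim 1
  sx <- shift_mat(g, -1, 0) - shift_mat(g, 1, 0)
  gx <- shift_mat(sx, 0, 1) + 2 * sx + shift_mat(sx, 0, -1)
  sy <- shift_mat(g, 0, -1) - shift_mat(g, 0, 1)
  gy <- shift_mat(sy, 1, 0) + 2 * sy + shift_mat(sy, -1, 0)
  mag <- sqrt(gx^2 + gy^2)
  ## non-maximum suppression in 4 quantised gradient directions
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: x, 1: diag, 2: y, 3: anti-diag
  nms <- mag
  off <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  for (s in 0:3) {
    d <- off[[s + 1]]
    keep <- mag >= shift_mat(mag, d[1], d[2]) & mag >= shift_mat(mag, -d[1], -d[2])
    nms[sector == s & !keep] <- 0
  }
  strong <- nms >= hi
  weak <- nms >= lo
  if (!any(strong)) return(strong)
  lbl <- label8(weak)
  keep_lbl <- unique(lbl[strong])
  weak & matrix(lbl %in% keep_lbl, nrow(lbl), ncol(lbl))
}

#' Edge image of a regional slide
#'
#' Grey value = nuclear count x 20, clipped to 8 bits; Canny parameters from
#' the edge-detection table (Gaussian sd 3, Sobel radius 1, hysteresis 50/30).
#'
#' @param slide a [regional_slide()].
#' @param cfg a [pipeline_config()].
#' @return list with `points` (n x 2 matrix of 0-based (x, y) region-pixel
#'   coordinates; may be empty), `dims`, and `empty` flag.
#' @export
edge_image <- function(slide, cfg = pipeline_config()) {
  grey <- pmin(slide$count * cfg$count_scale, 255)
  if (!any(grey > 0))
    return(list(points = matrix(numeric(0), 0, 2), dims = dim(grey), empty = TRUE))
  e <- canny_edges(grey, cfg$canny_sigma, cfg$canny_hi, cfg$canny_lo)
  idx <- which(e, arr.ind = TRUE)
  list(points = cbind(x = idx[, 1] - 1, y = idx[, 2] - 1), dims = dim(grey),
       empty = nrow(idx) == 0L)
}

## ---- coincidence scoring -------------------------------------------------

## Occupancy lookup of the reference set dilated by 1 px (the matching
## radius), over the frame plus a 64-px margin for transformed points.
occ_lookup <- function(E0, dims) {
  m <- 64L
  W <- as.integer(dims[1]) + 2L * m; H <- as.integer(dims[2]) + 2L * m
  occ <- logical(W * H)
  exact <- logical(W * H)
  x <- as.integer(round(E0[, 1])) + m; y <- as.integer(round(E0[, 2])) + m
  oke <- x >= 0L & x < W & y >= 0L & y < H
  exact[(x + W * y)[oke] + 1L] <- TRUE
  x9 <- rep(x, each = 9L) + rep(c(-1L, 0L, 1L), times = 3L)
  y9 <- rep(y, each = 9L) + rep(c(-1L, 0L, 1L), each = 3L)
  ok <- x9 >= 0L & x9 < W & y9 >= 0L & y9 < H
  occ[(x9 + W * y9)[ok] + 1L] <- TRUE
  list(occ = occ, exact = exact, W = W, H = H, m = m)
}

## 1-px-tolerance hit count, with the exact-bin hit count as a fractional
## tiebreaker (prefers sub-tolerance alignment without changing the integer
## objective).
score_occ <- function(px, py, lk) {
  x <- as.integer(round(px)) + lk$m; y <- as.integer(round(py)) + lk$m
  ok <- x >= 0L & x < lk$W & y >= 0L & y < lk$H
  keys <- (x + lk$W * y)[ok] + 1L
  sum(lk$occ[keys]) + sum(lk$exact[keys]) / (length(px) + 1)
}

#' Edge coincidence score between two point sets
#'
#' Number of points of `E1` landing within 1 px of a point of `E0` after
#' rounding (the matching radius used throughout the rigid registration).
#' @param E1,E0 n x 2 point matrices.
#' @param dims frame dims.
#' @return integer count.
#' @export
coincidence_score <- function(E1, E0, dims) {
  if (!nrow(E1) || !nrow(E0)) return(0L)
  score_occ(E1[, 1], E1[, 2], occ_lookup(E0, dims))
}

#' Hough translation search
#'
#' Accumulates integer offsets `t = q - p` over all edge-point pairs with
#' `|t|_inf <= bound` and returns the offset with the highest count; ties go
#' to the smallest `|t|` (Euclidean), then lexicographically.
#'
#' @param E1 edge points of the moving slide (n x 2).
#' @param E0 edge points of the reference (m x 2).
#' @param bound max |t| per axis, px.
#' @return `c(tx, ty)`.
#' @export
hough_translate <- function(E1, E0, bound) {
  if (!nrow(E1) || !nrow(E0)) stop("no edges")
  p <- round(E1); q <- round(E0)
  dx <- rep(q[, 1], times = nrow(p)) - rep(p[, 1], each = nrow(q))
  dy <- rep(q[, 2], times = nrow(p)) - rep(p[, 2], each = nrow(q))
  ok <- abs(dx) <= bound & abs(dy) <= bound
  if (!any(ok)) return(c(0, 0))
  dx <- dx[ok]; dy <- dy[ok]
  B <- as.integer(bound)
  key <- (dx + B) * (2L * B + 1L) + (dy + B)
  tab <- tabulate(key + 1L, nbins = (2L * B + 1L)^2)
  best <- which(tab == max(tab)) - 1L
  bx <- best %/% (2L * B + 1L) - B
  by <- best %% (2L * B + 1L) - B
  o <- order(bx^2 + by^2, bx, by)
  c(bx[o[1]], by[o[1]])
}

#' Hough rotation search over a grid of centres
#'
#' Rotating a point set about a centre is a shift along the angle axis of its
#' polar transform; equivalently, each candidate (theta, centre) is scored by
#' the number of rotated moving-set points landing within the 1-px matching
#' tolerance of the reference set. The candidate grid spans `|theta| <=
#' bound` at resolution `res_deg` (coarse early, fine once the bound
#' narrows). Ties go to the smaller |theta|, then the centre nearest `c0`.
#'
#' @param E1,E0 edge point matrices.
#' @param centres k x 2 matrix of rotation centres.
#' @param bound max |theta| in degrees.
#' @param c0 frame centre (tie-breaking).
#' @param res_deg candidate angular resolution, degrees.
#' @param dims frame dims (for the coincidence keys); defaults to the point
#'   extent.
#' @return list `theta` (deg), `centre`, `score`.
#' @export
hough_rotate <- function(E1, E0, centres, bound, c0, res_deg = 1,
                         dims = NULL) {
  if (!nrow(E1) || !nrow(E0)) stop("no edges")
  if (is.null(dims)) dims <- apply(rbind(E0, E1, centres), 2, max) + 2
  thetas <- seq(-bound, bound, by = res_deg)
  thetas <- thetas[order(abs(thetas), thetas)]  # visit small |theta| first
  lk <- occ_lookup(E0, dims)
  best <- list(theta = 0, centre = c0, score = -1L)
  for (ci in seq_len(nrow(centres))) {
    cc <- centres[ci, ]
    px <- E1[, 1] - cc[1]; py <- E1[, 2] - cc[2]
    for (th in thetas) {
      a <- th * pi / 180
      sc <- score_occ(cos(a) * px - sin(a) * py + cc[1],
                      sin(a) * px + cos(a) * py + cc[2], lk)
      if (sc > best$score ||
          (sc == best$score && (abs(th) < abs(best$theta) ||
            (abs(th) == abs(best$theta) &&
             sum((cc - c0)^2) < sum((best$centre - c0)^2))))) {
        best <- list(theta = th, centre = cc, score = sc)
      }
    }
  }
  best
}

## Rotation-centre grid for a transformation step.
rotation_centres <- function(step, dims, cfg) {
  c0 <- (dims - 1) / 2
  pitch <- cfg$rigid_centre_pitch * step
  if (step == 1) lim <- cfg$rigid_centre_r1 else lim <- max(dims)
  nx <- floor(lim / pitch)
  offs <- seq.int(-nx, nx) * pitch
  g <- expand.grid(x = c0[1] + offs, y = c0[2] + offs)
  g <- g[g$x >= 0 & g$x < dims[1] & g$y >= 0 & g$y < dims[2], , drop = FALSE]
  if (step == 1) {
    keep <- abs(g$x - c0[1]) <= cfg$rigid_centre_r1 & abs(g$y - c0[2]) <= cfg$rigid_centre_r1
    g <- g[keep, , drop = FALSE]
  }
  unique(as.matrix(rbind(data.frame(x = c0[1], y = c0[2]), g)))
}

## Apply rotation by theta (deg) about centre to points.
rotate_pts <- function(p, theta, centre) {
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sweep(sweep(p, 2, centre) %*% t(R), 2, centre, "+")
}

#' Rigid transform record
#' @param theta rotation, deg. @param t translation `c(tx, ty)`, px.
#' @param centre rotation centre.
#' @return a `rigid_transform` list.
#' @export
rigid_transform <- function(theta = 0, t = c(0, 0), centre = c(0, 0)) {
  structure(list(theta = theta, t = t, centre = centre), class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()]. @param p n x 2 point matrix.
#' @return transformed points.
#' @export
apply_rigid <- function(tf, p) {
  if (!nrow(p)) return(p)
  sweep(rotate_pts(p, tf$theta, tf$centre), 2, tf$t, "+")
}

#' Register one edge set to a reference by the stepped Hough schedule
#'
#' Seven transformation steps; in step i the translation bound is `W / 2^i`
#' (W = frame width) and the rotation bound follows the printed sequence
#' (+-180, 10, 5, 2.5, 1.25, 1, and 1 again for step 7). Each step iterates
#' translate-then-rotate until nothing changes or 10 iterations; every applied
#' move must not decrease the 1-px-tolerance coincidence score.
#'
#' @param E1 moving edge points. @param E0 reference edge points.
#' @param dims frame dims. @param cfg a [pipeline_config()].
#' @return list `transform` (accumulated [rigid_transform()] with centre at
#'   the frame centre), `score`, `points` (transformed edge set).
#' @export
rigid_register_pair <- function(E1, E0, dims, cfg = pipeline_config()) {
  c0 <- (dims - 1) / 2
  cur <- E1
  A <- diag(2); d <- c(0, 0)   # accumulated affine p -> A p + d
  compose <- function(theta, centre, t) {
    th <- theta * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    d <<- as.vector(R %*% (d - centre)) + centre + t
    A <<- R %*% A
  }
  score <- coincidence_score(cur, E0, dims)
  for (step in seq_len(cfg$rigid_steps)) {
    tb <- dims[1] / 2^step
    rb <- cfg$rigid_rot_bounds[min(step, length(cfg$rigid_rot_bounds))]
    res_deg <- if (rb > 5) 1 else max(0.25, rb / 5)
    centres <- rotation_centres(step, dims, cfg)
    for (it in seq_len(cfg$rigid_max_iter)) {
      changed <- FALSE
      t <- hough_translate(cur, E0, tb)
      if (any(t != 0)) {
        cand <- sweep(cur, 2, t, "+")
        sc <- coincidence_score(cand, E0, dims)
        if (sc >= score) { cur <- cand; score <- sc; compose(0, c0, t); changed <- TRUE }
      }
      rot <- hough_rotate(cur, E0, centres, rb, c0, res_deg, dims)
      if (rot$theta != 0) {
        cand <- rotate_pts(cur, rot$theta, rot$centre)
        sc <- coincidence_score(cand, E0, dims)
        if (sc >= score) {
          cur <- cand; score <- sc; compose(rot$theta, rot$centre, c(0, 0)); changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  theta <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  ## express as rotation about c0 plus translation: p -> R (p - c0) + c0 + t
  t <- d - (c0 - as.vector(A %*% c0))
  list(transform = rigid_transform(theta, t, c0), score = score, points = cur)
}

#' Rigid registration of a slide stack
#'
#' Registers each slide's edge image to its (already registered) predecessor.
#' Slides with empty edge sets are passed through unregistered and flagged;
#' the next slide then registers to the last slide with edges.
#'
#' @param slides list of [regional_slide()] objects.
#' @param cfg a [pipeline_config()].
#' @param qc_dir optional directory for composite edge overlay PNGs.
#' @return list with `transforms` (per-slide [rigid_transform()]),
#'   `flags` (per-slide: `"ok"` / `"empty"`), `scores`.
#' @export
rigid_register_stack <- function(slides, cfg = pipeline_config(), qc_dir = NULL) {
  ns <- length(slides)
  stopifnot(ns >= 2)
  dims <- dim(slides[[1]]$category)
  transforms <- replicate(ns, rigid_transform(centre = (dims - 1) / 2), simplify = FALSE)
  flags <- rep("ok", ns); scores <- rep(NA_real_, ns)
  edges <- lapply(slides, edge_image, cfg = cfg)
  ref_pts <- NULL
  for (s in seq_len(ns)) {
    E <- edges[[s]]$points
    if (!nrow(E)) { flags[s] <- "empty"; next }
    if (is.null(ref_pts)) { ref_pts <- E; next }
    r <- rigid_register_pair(E, ref_pts, dims, cfg)
    transforms[[s]] <- r$transform
    scores[s] <- r$score
    if (!is.null(qc_dir)) write_edge_overlay(r$points, ref_pts, dims,
      file.path(qc_dir, sprintf("rigid_overlay_%03d.png", slides[[s]]$slide_number)))
    ref_pts <- r$points
  }
  list(transforms = transforms, flags = flags, scores = scores)
}

## QC overlay: sum of the two edge images (moving = red, reference = green).
write_edge_overlay <- function(E1, E0, dims, path) {
  img <- array(0, c(dims[2], dims[1], 3))
  put <- function(E, ch) {
    p <- round(E)
    ok <- p[, 1] >= 0 & p[, 1] < dims[1] & p[, 2] >= 0 & p[, 2] < dims[2]
    img[cbind(p[ok, 2] + 1, p[ok, 1] + 1, ch)] <<- 1
  }
  put(E1, 1); put(E0, 2)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(img, path)
  invisible(path)
}
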