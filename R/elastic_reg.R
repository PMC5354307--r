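## Elastic-registration stage (with reference ordering): locally rigid per-tile registration.
##
## Slides are divided into 16 x 16 region-pixel tiles. Each tile's search
## area grows until its direction field is heterogeneous enough (angle
## variance >= (45 deg)^2) to anchor a match; a Hough accumulator over
## (theta, t) pairs bounded by the angle-compatibility rule and the
## energy-scaled elasticity b(A) = b0 * e(A, T0) finds the local transform;
## neighbourhood comparison replaces transforms that a neighbour beats; and
## nuclei are finally warped by an inverse-square-distance blend of the four
## nearest tile transforms. Only planar pixels carry shape information here -
## vertical and empty pixels are both treated as featureless.

#' Heterogeneity of a direction-field area
#'
#' Builds the filled angle sequence S: planar pixels contribute their own
#' angle, every non-planar pixel contributes the angle perpendicular to the
#' circular mean of the planar angles. Returns the circular (Frechet)
#' variance of S in squared degrees. Zero planar pixels give 0 (flagged by
#' attribute `degenerate`).
#'
#' @param category integer vector/matrix of pixel categories in the area.
#' @param theta planar angles (deg), `NA` where not planar.
#' @return variance in deg^2.
#' @export
heterogeneity <- function(category, theta) {
  pl <- category == CAT_PLANAR
  n <- length(category)
  if (!any(pl)) return(structure(0, degenerate = TRUE))
  th <- theta[pl]
  tbar <- circ_mean180(th)
  if (is.na(tbar)) tbar <- circ_median180(th)
  S <- c(th, rep(ang_norm180(tbar + 90), n - sum(pl)))
  circ_var180(S)
}

## Tile area as an index rectangle [x0, x1] x [y0, y1] (1-based, inclusive),
## grown by whole tile rings until heterogeneous enough or frame exhausted.
tile_area <- function(slide, tx, ty, cfg) {
  tp <- cfg$tile_px
  d <- dim(slide$category)
  ring <- 0L
  repeat {
    x0 <- max(1L, (tx - 1L - ring) * tp + 1L); x1 <- min(d[1], (tx + ring) * tp)
    y0 <- max(1L, (ty - 1L - ring) * tp + 1L); y1 <- min(d[2], (ty + ring) * tp)
    het <- heterogeneity(slide$category[x0:x1, y0:y1], slide$theta[x0:x1, y0:y1])
    full <- x0 == 1L && y0 == 1L && x1 == d[1] && y1 == d[2]
    if (het >= cfg$het_min_deg2 || full)
      return(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, heterogeneity = as.numeric(het)))
    ring <- ring + 1L
  }
}

## Pixel lists of an area: 0-based centre coordinates, categories, angles.
area_pixels <- function(slide, area) {
  xs <- area$x0:area$x1; ys <- area$y0:area$y1
  g <- expand.grid(x = xs - 1L, y = ys - 1L)
  cat <- as.vector(slide$category[xs, ys])
  th <- as.vector(slide$theta[xs, ys])
  list(x = g$x, y = g$y, planar = cat == CAT_PLANAR, theta = th)
}

#' Match energy of a transformed area against a reference slide
#'
#' A pixel p is matched if any of the four reference pixels around T(p)
#' (floor plus `{0,1}^2`) is category-compatible: both non-planar, or both
#' planar with headless angle difference below `a_max` after adding the
#' transform's rotation. The energy is `1 - N_matched / N` (0 = perfect).
#'
#' @param px area pixels from `area_pixels()`.
#' @param ref reference [regional_slide()].
#' @param theta,t transform (deg; px translation).
#' @param cfg a [pipeline_config()].
#' @return energy in `[0, 1]`.
#' @export
match_energy <- function(px, ref, theta = 0, t = c(0, 0), cfg = pipeline_config()) {
  n <- length(px$x)
  if (n == 0L) return(0)
  d <- dim(ref$category)
  thr <- theta * pi / 180
  Tx <- cos(thr) * px$x - sin(thr) * px$y + t[1]
  Ty <- sin(thr) * px$x + cos(thr) * px$y + t[2]
  fx <- floor(Tx); fy <- floor(Ty)
  matched <- rep(FALSE, n)
  for (ox in 0:1) for (oy in 0:1) {
    qx <- fx + ox; qy <- fy + oy
    inb <- qx >= 0 & qx < d[1] & qy >= 0 & qy < d[2]
    qcat <- rep(CAT_EMPTY, n); qth <- rep(NA_real_, n)
    ii <- cbind(qx[inb] + 1L, qy[inb] + 1L)
    qcat[inb] <- ref$category[ii]
    qth[inb] <- ref$theta[ii]
    qpl <- qcat == CAT_PLANAR
    m <- (!px$planar & !qpl) |
      (px$planar & qpl & ang_dist180(qth, px$theta + theta) < cfg$a_max)
    m[is.na(m)] <- FALSE
    matched <- matched | m
  }
  1 - sum(matched) / n
}

#' Register one tile area to the reference slide
#'
#' If the identity energy is at most `e_min` the tile keeps the identity.
#' Otherwise a Hough accumulator over integer-degree rotations
#' (|theta| <= 30) and 1-px translation bins `t = q - M_theta p`, restricted
#' to angle-compatible point pairs and `|t| <= b0 * e(A, T0)`, picks the
#' densest bin (ties: smaller |theta|, then smaller |t|, then lexicographic).
#'
#' @param slide moving [regional_slide()]. @param ref reference slide.
#' @param tx,ty tile indices (1-based). @param cfg a [pipeline_config()].
#' @return list `theta`, `t`, `energy` (identity energy), `area`, `flag`.
#' @export
register_tile <- function(slide, ref, tx, ty, cfg = pipeline_config()) {
  area <- tile_area(slide, tx, ty, cfg)
  px <- area_pixels(slide, area)
  e0 <- match_energy(px, ref, 0, c(0, 0), cfg)
  out <- list(theta = 0, t = c(0, 0), energy = e0, area = area, flag = "identity")
  if (e0 <= cfg$e_min) return(out)
  b <- cfg$b0 * e0
  p1 <- which(px$planar)
  if (!length(p1)) { out$flag <- "no_planar"; return(out) }
  ## reference planar pixels within reach of the area
  d <- dim(ref$category)
  xr <- max(1L, floor(area$x0 - b - 1)):min(d[1], ceiling(area$x1 + b + 1))
  yr <- max(1L, floor(area$y0 - b - 1)):min(d[2], ceiling(area$y1 + b + 1))
  refcat <- ref$category[xr, yr]
  q <- which(refcat == CAT_PLANAR, arr.ind = TRUE)
  if (!nrow(q)) { out$flag <- "no_reference"; return(out) }
  qx <- xr[q[, 1]] - 1L; qy <- yr[q[, 2]] - 1L
  qth <- ref$theta[cbind(xr[q[, 1]], yr[q[, 2]])]
  h <- cpp_tile_hough(px$x[p1], px$y[p1], px$theta[p1], qx, qy, qth,
                      b, cfg$a_max, as.integer(cfg$elastic_theta_max))
  if (!h$found) { out$flag <- "no_admissible"; return(out) }
  out$theta <- h$theta; out$t <- c(h$tx, h$ty); out$flag <- "hough"
  out
}

#' Elastic registration of one slide to a reference
#'
#' Per-tile registration followed by 3 x 3 neighbourhood refinement: each
#' tile takes, from the transforms of its neighbourhood, the one minimising
#' the summed energy over the neighbourhood's areas (simultaneous update from
#' the original assignment).
#'
#' @param slide,ref [regional_slide()] objects.
#' @param cfg a [pipeline_config()].
#' @return list with `tiles` (ntx x nty list-matrix of transforms),
#'   `centres` (tile centres, 0-based px), `ntx`, `nty`.
#' @export
elastic_register_slide <- function(slide, ref, cfg = pipeline_config()) {
  d <- dim(slide$category); tp <- cfg$tile_px
  ntx <- ceiling(d[1] / tp); nty <- ceiling(d[2] / tp)
  tiles <- vector("list", ntx * nty)
  dim(tiles) <- c(ntx, nty)
  occupied <- matrix(FALSE, ntx, nty)
  for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
    x0 <- (tx - 1L) * tp + 1L; x1 <- min(d[1], tx * tp)
    y0 <- (ty - 1L) * tp + 1L; y1 <- min(d[2], ty * tp)
    occupied[tx, ty] <- any(slide$category[x0:x1, y0:y1] != CAT_EMPTY)
    tiles[[tx, ty]] <- if (occupied[tx, ty]) register_tile(slide, ref, tx, ty, cfg)
      else list(theta = 0, t = c(0, 0), energy = 0, area = NULL, flag = "empty")
  }
  ## neighbourhood refinement
  px_cache <- vector("list", ntx * nty); dim(px_cache) <- c(ntx, nty)
  for (ty in seq_len(nty)) for (tx in seq_len(ntx))
    if (occupied[tx, ty]) px_cache[[tx, ty]] <- area_pixels(slide, tiles[[tx, ty]]$area)
  refined <- tiles
  rr <- cfg$refine_radius
  for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
    if (!occupied[tx, ty]) next
    nbx <- max(1L, tx - rr):min(ntx, tx + rr)
    nby <- max(1L, ty - rr):min(nty, ty + rr)
    cand <- list(); seen <- character(0)
    for (j in nby) for (i in nbx) if (occupied[i, j]) {
      tr <- tiles[[i, j]]
      key <- paste(tr$theta, tr$t[1], tr$t[2])
      if (!key %in% seen) { seen <- c(seen, key); cand[[length(cand) + 1L]] <- tr }
    }
    if (length(cand) < 2L) next
    tot <- vapply(cand, function(tr) {
      s <- 0
      for (j in nby) for (i in nbx) if (occupied[i, j])
        s <- s + match_energy(px_cache[[i, j]], ref, tr$theta, tr$t, cfg)
      s
    }, numeric(1))
    b <- cand[[which.min(tot)]]
    refined[[tx, ty]]$theta <- b$theta
    refined[[tx, ty]]$t <- b$t
  }
  centres_x <- ((seq_len(ntx) - 1L) * tp + (tp - 1) / 2)
  centres_y <- ((seq_len(nty) - 1L) * tp + (tp - 1) / 2)
  list(tiles = refined, centres_x = centres_x, centres_y = centres_y,
       ntx = ntx, nty = nty, tile_px = tp)
}

#' Warp points by blended tile transforms
#'
#' Each point is mapped to `sum_i w_i (M_theta_i p + t_i)` over its four
#' nearest tile centres, with weights `w_i` proportional to the inverse
#' squared distance to each centre (a point on a centre takes that tile's
#' transform exactly). Angles, if supplied, are rotated by the weighted mean
#' tile rotation.
#'
#' @param p n x 2 matrix of points (0-based region-pixel coordinates).
#' @param reg result of [elastic_register_slide()].
#' @param angles optional headless angles to co-rotate.
#' @return warped points (and `attr(,"angles")` if angles were given).
#' @export
apply_warp <- function(p, reg, angles = NULL) {
  if (!nrow(p)) return(p)
  cx <- reg$centres_x; cy <- reg$centres_y
  out <- matrix(0, nrow(p), 2)
  outang <- if (!is.null(angles)) numeric(nrow(p)) else NULL
  for (i in seq_len(nrow(p))) {
    ## 2 nearest centres per axis = 4 nearest tile centres on a regular grid
    ix <- order(abs(cx - p[i, 1]))[1:min(2, length(cx))]
    iy <- order(abs(cy - p[i, 2]))[1:min(2, length(cy))]
    g <- expand.grid(ix = ix, iy = iy)
    d2 <- (cx[g$ix] - p[i, 1])^2 + (cy[g$iy] - p[i, 2])^2
    if (any(d2 < 1e-12)) { w <- as.numeric(d2 < 1e-12); w <- w / sum(w) }
    else { w <- 1 / d2; w <- w / sum(w) }
    ## blended as p + sum w_i (T_i(p) - p): identity tiles contribute exactly
    ## nothing, so an all-identity warp is the exact identity map
    acc <- c(0, 0); thw <- 0
    for (k in seq_len(nrow(g))) {
      tr <- reg$tiles[[g$ix[k], g$iy[k]]]
      thr <- tr$theta * pi / 180
      Tp <- c(cos(thr) * p[i, 1] - sin(thr) * p[i, 2] + tr$t[1],
              sin(thr) * p[i, 1] + cos(thr) * p[i, 2] + tr$t[2])
      acc <- acc + w[k] * (Tp - p[i, ])
      thw <- thw + w[k] * tr$theta
    }
    out[i, ] <- p[i, ] + acc
    if (!is.null(outang)) outang[i] <- ang_norm180(angles[i] + thw)
  }
  if (!is.null(outang)) attr(out, "angles") <- outang
  out
}

#' Match score between two regional slides
#'
#' `1 - #(non-empty in both) / mean(#non-empty)`; 0 = perfectly matched,
#' 1 = disjoint (or both empty).
#' @param s1,s2 [regional_slide()] objects.
#' @return score in `[0, 1]`.
#' @export
match_score <- function(s1, s2) {
  a <- s1$category != CAT_EMPTY; b <- s2$category != CAT_EMPTY
  denom <- (sum(a) + sum(b)) / 2
  if (denom == 0) return(1)
  max(0, 1 - sum(a & b) / denom)
}

#' Reference ordering, elastic registration and QC of a rigidly aligned stack
#'
#' Chooses the global reference slide as the least-distorted slide of the
#' densest substack (largest mean non-empty count over `substack_len`
#' consecutive slides), picks local references outward in groups of
#' `ref_spacing` by best match score to the previous reference, registers
#' references to the previous reference and every other slide to its nearest
#' reference, and flags slides whose post-registration match score exceeds
#' `qc_discard_score`. A failed reference is discarded and replaced by the
#' next-best slide of its group; registration for that group re-runs from the
#' last good reference.
#'
#' @param stack list of per-slide lists with elements `ellipses` (region-pixel
#'   coordinates in `$rx, $ry`, angles in `$theta`) and `regional`
#'   (a [regional_slide()]); rigid registration already applied.
#' @param cfg a [pipeline_config()].
#' @return list with `slides` (registered regional slides), `ellipses`
#'   (warped per-slide tables), `reference` (global reference index),
#'   `references` (logical), `discard` (logical), `scores`.
#' @export
order_and_register <- function(stack, cfg = pipeline_config()) {
  ns <- length(stack)
  if (ns < 3) stop("need at least 3 slides")
  regs <- lapply(stack, `[[`, "regional")
  counts <- vapply(regs, function(s) sum(s$category != CAT_EMPTY), numeric(1))
  L <- min(cfg$substack_len, ns)
  win_means <- vapply(seq_len(ns - L + 1L),
                      function(i) mean(counts[i:(i + L - 1L)]), numeric(1))
  w0 <- which.max(win_means)
  sub <- w0:(w0 + L - 1L)
  pair_scores <- sapply(sub, function(i)
    mean(vapply(setdiff(sub, i), function(j) match_score(regs[[i]], regs[[j]]), numeric(1))))
  ## ties: prefer the slide nearest the middle of the substack, then lower index
  ord <- order(pair_scores, abs(sub - stats::median(sub)), sub)
  gref <- sub[ord[1]]
  ## local reference selection outward in groups
  is_ref <- rep(FALSE, ns); is_ref[gref] <- TRUE
  ref_of <- rep(NA_integer_, ns)
  pick_refs <- function(idx_seq) {
    prev <- gref
    groups <- split(idx_seq, ceiling(seq_along(idx_seq) / cfg$ref_spacing))
    for (grp in groups) {
      sc <- vapply(grp, function(i) match_score(regs[[i]], regs[[prev]]), numeric(1))
      r <- grp[which.min(sc)]
      is_ref[r] <<- TRUE
      ref_of[r] <<- prev
      prev <- r
    }
  }
  if (gref < ns) pick_refs((gref + 1L):ns)
  if (gref > 1L) pick_refs(rev(seq_len(gref - 1L)))
  refs <- which(is_ref)
  for (i in seq_len(ns)) if (!is_ref[i])
    ref_of[i] <- refs[which.min(abs(refs - i))]
  ## registration, references first (outward), then the rest
  out_regs <- regs; out_ell <- lapply(stack, `[[`, "ellipses")
  discard <- rep(FALSE, ns); scores <- rep(NA_real_, ns)
  register_one <- function(i, ref_idx) {
    reg <- elastic_register_slide(regs[[i]], out_regs[[ref_idx]], cfg)
    e <- stack[[i]]$ellipses
    p <- apply_warp(cbind(e$rx, e$ry), reg, angles = e$theta)
    e$rx <- p[, 1]; e$ry <- p[, 2]
    e$theta <- attr(p, "angles")
    rs <- regrid_regional(e, regs[[i]], cfg)
    list(reg = rs, ell = e, score = match_score(rs, out_regs[[ref_idx]]))
  }
  order_refs <- refs[order(abs(refs - gref))]
  for (i in setdiff(order_refs, gref)) {
    r <- register_one(i, ref_of[i])
    scores[i] <- r$score
    if (r$score > cfg$qc_discard_score) {
      discard[i] <- TRUE
      is_ref[i] <- FALSE
    } else {
      out_regs[[i]] <- r$reg; out_ell[[i]] <- r$ell
    }
  }
  refs <- which(is_ref)
  for (i in seq_len(ns)) if (!is_ref[i]) {
    ref_idx <- refs[which.min(abs(refs - i))]
    r <- register_one(i, ref_idx)
    scores[i] <- r$score
    if (r$score > cfg$qc_discard_score) discard[i] <- TRUE
    else { out_regs[[i]] <- r$reg; out_ell[[i]] <- r$ell }
  }
  list(slides = out_regs, ellipses = out_ell, reference = gref,
       references = is_ref, discard = discard, scores = scores)
}

## Rebuild a regional slide from warped nuclei kept in region-pixel
## coordinates (rx, ry), on the same frame as `template`.
regrid_regional <- function(e, template, cfg) {
  d <- dim(template$category)
  W <- d[1]; H <- d[2]
  cat <- matrix(CAT_EMPTY, W, H); theta <- matrix(NA_real_, W, H)
  count <- matrix(0, W, H); count_all <- matrix(0, W, H); count_small <- matrix(0, W, H)
  sc2 <- matrix(0, W, H); ss2 <- matrix(0, W, H)
  if (nrow(e)) {
    gx <- floor(e$rx) + 1L; gy <- floor(e$ry) + 1L
    ok <- gx >= 1L & gx <= W & gy >= 1L & gy <= H
    key <- (gx - 1L) + W * (gy - 1L)
    for (k in split(which(ok), key[ok])) {
      cl <- classify_region(e[k, , drop = FALSE], cfg)
      i <- gx[k[1]]; j <- gy[k[1]]
      cat[i, j] <- cl$category; theta[i, j] <- cl$theta
      count[i, j] <- cl$count; count_all[i, j] <- cl$count_all
      count_small[i, j] <- cl$count_small
      sc2[i, j] <- cl$sum_cos2; ss2[i, j] <- cl$sum_sin2
    }
  }
  regional_slide(cat, theta, count, count_all, count_small,
                 template$slide_number, template$um_per_pixel, sc2, ss2)
}
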