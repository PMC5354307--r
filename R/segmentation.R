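## Segmentation stage: watershed-with-merging segmentation on double-angle anisotropy
## images.
##
## Headless directions cannot be averaged directly (v and -v cancel), so
## angles are doubled before Gaussian smoothing: in 2-D
## v' = (cos 2theta, sin 2theta); in 3-D three transforms v^(i) = 2 v_i v - e_i
## double the angle from each axis. The anisotropy image
## I_w(p) = sum_jk g_j g_k w_j w_k (2 (v_j . v_k)^2 - 1) (factor 4 in 3-D)
## then has closed forms in terms of the convolved double-angle fields, and
## the pool-merging comparison f(p, q) likewise. Flooding in order of
## decreasing anisotropy with merging where neighbourhood fields agree
## (f >= f_min) suppresses over-segmentation while keeping boundaries closed.

## ---- watershed with merging ---------------------------------------------

#' Watershed with merging
#'
#' Floods points in descending order of `values` (ties by raster index).
#' A point adjacent to two or more pools becomes a watershed point only if
#' some pair of those pools' maxima has `f < f_min`; otherwise the pools
#' merge through it. Adjacency is face adjacency (4 in 2-D, 6 in 3-D).
#'
#' @param values numeric matrix or 3-D array (the anisotropy image).
#' @param mask logical same-shape; `FALSE` points are excluded (labelled 0).
#' @param f function `(p_idx, q_idx) -> numeric` comparing the two pools'
#'   maxima (linear indices), or a constant.
#' @param f_min merge threshold.
#' @return integer array of the same shape: pool labels >= 1, 0 for masked
#'   points, -1 for watershed points. Attribute `maxima` holds each pool's
#'   first (highest) point.
#' @export
watershed_merge <- function(values, mask = NULL, f = 0, f_min = 0.5) {
  d <- dim(values)
  nd <- length(d)
  if (is.null(mask)) mask <- array(TRUE, d)
  f_fun <- if (is.function(f)) f else function(p, q) f
  idx <- which(mask)
  ord <- idx[order(-values[idx], idx)]
  lab <- array(0L, d)
  parent <- integer(0)       # union-find over pool ids
  pool_max <- integer(0)     # first point of each pool
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ## face-neighbour linear offsets with bounds handling via coordinates
  nbrs <- function(lin) {
    if (nd == 2L) {
      x <- (lin - 1L) %% d[1] + 1L; y <- (lin - 1L) %/% d[1] + 1L
      out <- c(if (x > 1) lin - 1L, if (x < d[1]) lin + 1L,
               if (y > 1) lin - d[1], if (y < d[2]) lin + d[1])
    } else {
      pl <- d[1] * d[2]
      r <- (lin - 1L) %% pl
      x <- r %% d[1] + 1L; y <- r %/% d[1] + 1L; z <- (lin - 1L) %/% pl + 1L
      out <- c(if (x > 1) lin - 1L, if (x < d[1]) lin + 1L,
               if (y > 1) lin - d[1], if (y < d[2]) lin + d[1],
               if (z > 1) lin - pl, if (z < d[3]) lin + pl)
    }
    out
  }
  for (p in ord) {
    ls <- lab[nbrs(p)]
    ls <- unique(vapply(ls[ls > 0L], find, integer(1)))
    if (length(ls) == 0L) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      pool_max[length(pool_max) + 1L] <- p
      lab[p] <- length(parent)
    } else if (length(ls) == 1L) {
      lab[p] <- ls
    } else {
      split_pair <- FALSE
      for (a in seq_along(ls)) for (b in seq_along(ls)) if (a < b) {
        if (f_fun(pool_max[ls[a]], pool_max[ls[b]]) < f_min) { split_pair <- TRUE }
      }
      if (split_pair) {
        lab[p] <- -1L
      } else {
        root <- min(ls)
        for (l in ls) parent[l] <- root
        lab[p] <- root
      }
    }
  }
  pos <- which(lab > 0L)
  roots <- vapply(lab[pos], find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[pos] <- relab
  structure(out, maxima = pool_max)
}

## ---- 2-D anisotropy ------------------------------------------------------

#' Grey images for 2-D segmentation of a regional slide
#'
#' Vertical channel: vertical-pixel counts Gaussian-smoothed (variance 1);
#' edge points are below-threshold points face-adjacent to above-threshold
#' points. Planar channel: the double-angle field `V' = count (cos 2theta,
#' sin 2theta)` smoothed with the same Gaussian; `I_w = |G * V'_w|^2`, with
#' points below the planar grey threshold masked.
#'
#' @param slide a [regional_slide()].
#' @param cfg a [pipeline_config()].
#' @return list with `vertical_edges` (logical), `I_w`, `mask` (points kept
#'   for the watershed), and cached convolutions `GVx`, `GVy`, `GW`.
#' @export
grey_2d <- function(slide, cfg = pipeline_config()) {
  sigma <- sqrt(cfg$seg2d_var)
  vert <- slide$count * (slide$category == CAT_VERTICAL)
  sv <- gauss_smooth(vert, sigma)
  above <- sv >= cfg$vert_grey_min
  nb <- shift_mat(above, 1, 0) | shift_mat(above, -1, 0) |
    shift_mat(above, 0, 1) | shift_mat(above, 0, -1)
  vertical_edges <- !above & nb
  pl <- slide$category == CAT_PLANAR
  w <- slide$count * pl
  th <- ifelse(pl, slide$theta, 0)
  GVx <- gauss_smooth(w * cospi(th / 90), sigma)
  GVy <- gauss_smooth(w * sinpi(th / 90), sigma)
  GW <- gauss_smooth(w, sigma)
  I_w <- GVx^2 + GVy^2
  list(vertical_edges = vertical_edges, I_w = I_w,
       mask = I_w >= cfg$planar_grey_min, GVx = GVx, GVy = GVy, GW = GW)
}

#' 2-D pool-comparison function (closed form)
#'
#' `f(p,q) = (|A(p)+A(q)|^2 - I_w(p) - I_w(q)) / (4 GW(p) GW(q)) + 1/2` with
#' `A = G*V'_w`; equals the normalised double sum of squared scalar products
#' between the two neighbourhoods' direction vectors. Zero weight at either
#' point gives 0 (nothing can merge through empty tissue).
#'
#' @param p,q linear indices. @param cache result of [grey_2d()].
#' @return f in `[0, 1]` (up to numerical noise).
#' @export
merge_f_2d <- function(p, q, cache) {
  D <- cache$GW[p] * cache$GW[q]
  if (!is.finite(D) || D <= 0) return(0)
  s2 <- (cache$GVx[p] + cache$GVx[q])^2 + (cache$GVy[p] + cache$GVy[q])^2
  (s2 - cache$I_w[p] - cache$I_w[q]) / (4 * D) + 0.5
}

#' Segment one slide in 2-D
#'
#' Planar watershed with merging (threshold `f_min_2d`) plus vertical edge
#' points; the combined edge set encases every bundle.
#'
#' @inheritParams grey_2d
#' @return list with `labels`, `edges` (logical: watershed + vertical edges +
#'   masked-out planar boundary), `cache`.
#' @export
segment_2d <- function(slide, cfg = pipeline_config()) {
  g <- grey_2d(slide, cfg)
  lab <- watershed_merge(g$I_w, mask = g$mask,
                         f = function(p, q) merge_f_2d(p, q, g),
                         f_min = cfg$f_min_2d)
  edges <- (lab == -1L) | g$vertical_edges
  list(labels = lab, edges = edges, cache = g)
}

## ---- 3-D anisotropy ------------------------------------------------------

## Double-angle transform about axis i (1..3): v^(i) = 2 v_i v - e_i.
double_angle_3d <- function(vec, i) {
  vi <- vec[, , , i]
  out <- array(0, dim(vec))
  for (k in 1:3) out[, , , k] <- 2 * vi * vec[, , , k]
  out[, , , i] <- out[, , , i] - 1
  ## empty voxels (zero vectors) must stay zero, not -e_i
  zero <- vec[, , , 1] == 0 & vec[, , , 2] == 0 & vec[, , , 3] == 0
  for (k in 1:3) { o <- out[, , , k]; o[zero] <- 0; out[, , , k] <- o }
  out
}

#' 3-D anisotropy volume and cached convolutions
#'
#' Builds the three weighted double-angle volumes `V_w^(i)`, convolves each
#' component (and the weight volume) with the Gaussian kernel, and returns
#' `I_w = (sum_i |G*V_w^(i)|^2 - (G*W)^2) / 2`, which equals the weighted
#' double-sum anisotropy.
#'
#' @param vec nx x ny x nz x 3 array of unit direction vectors (zero where
#'   empty).
#' @param weight same-shape weight array (0 where empty).
#' @param sigma Gaussian sd (scalar) or per-voxel array from
#'   [adaptive_sigma()].
#' @param sigma_grid internal: grid used when `sigma` is an array.
#' @return list with `I_w`, `GV` (list of 3 smoothed 3-vector arrays), `GW`.
#' @export
grey_3d <- function(vec, weight, sigma = 1, sigma_grid = NULL) {
  nz_ok <- weight > 0
  len <- sqrt(vec[, , , 1]^2 + vec[, , , 2]^2 + vec[, , , 3]^2)
  if (any(nz_ok & abs(len - 1) > 1e-6))
    stop("non-unit direction vector with positive weight")
  d4 <- dim(vec)
  GV <- vector("list", 3)
  smooth_comp <- function(a, sigma) gauss_smooth(a, sigma)
  if (is.array(sigma)) {
    ## per-voxel sigma: compute per-grid-sigma convolutions, pick per voxel
    grid <- sigma_grid
    pick <- match(round(sigma, 6), round(grid, 6))
    GW <- array(0, d4[1:3])
    for (i in 1:3) GV[[i]] <- array(0, d4)
    for (gi in seq_along(grid)) {
      sel <- pick == gi
      if (!any(sel)) next
      for (i in 1:3) {
        Vw <- double_angle_3d(vec, i)
        for (k in 1:3) {
          sm <- gauss_smooth(Vw[, , , k] * weight, grid[gi])
          comp <- GV[[i]][, , , k]; comp[sel] <- sm[sel]; GV[[i]][, , , k] <- comp
        }
      }
      smw <- gauss_smooth(weight, grid[gi])
      GW[sel] <- smw[sel]
    }
  } else {
    for (i in 1:3) {
      Vw <- double_angle_3d(vec, i)
      GV[[i]] <- array(0, d4)
      for (k in 1:3) GV[[i]][, , , k] <- smooth_comp(Vw[, , , k] * weight, sigma)
    }
    GW <- smooth_comp(weight, sigma)
  }
  S <- array(0, d4[1:3])
  for (i in 1:3) for (k in 1:3) S <- S + GV[[i]][, , , k]^2
  list(I_w = (S - GW^2) / 2, GV = GV, GW = GW)
}

#' 3-D pool-comparison function (closed form)
#'
#' `f(p,q) = (sum_i |A_i(p)+A_i(q)|^2 - 2 I_w(p) - GW(p)^2 - 2 I_w(q) -
#' GW(q)^2) / (8 GW(p) GW(q)) + 1/4`, equal to the normalised double sum of
#' squared scalar products between the two neighbourhoods.
#'
#' @param p,q linear voxel indices. @param cache result of [grey_3d()].
#' @return f value (0 when either neighbourhood is empty).
#' @export
merge_f_3d <- function(p, q, cache) {
  D <- cache$GW[p] * cache$GW[q]
  if (!is.finite(D) || D <= 0) return(0)
  s <- 0
  for (i in 1:3) for (k in 1:3) {
    comp <- cache$GV[[i]][, , , k]
    s <- s + (comp[p] + comp[q])^2
  }
  (s - 2 * cache$I_w[p] - cache$GW[p]^2 - 2 * cache$I_w[q] - cache$GW[q]^2) /
    (8 * D) + 0.25
}

#' Adaptive smoothing scale
#'
#' Minimises `d = lambda sigma^2 + eps(p, sigma)^2` over the sigma grid,
#' where `eps(p, sigma)^2` sums, over the first-order (face) neighbourhood
#' of p and p itself, the squared differences between the *smoothed*
#' weighted double-angle fields at the neighbours and the *raw* field at p -
#' i.e. how poorly the smoothed neighbourhood represents the voxel. In noisy
#' homogeneous tissue the smoothed neighbours approach the local mean and
#' eps falls as sigma grows, so wide bundles earn large kernels; across a
#' thin structure smoothing drags in empty surroundings and eps rises, so
#' thin bundles keep small kernels. A perfectly uniform volume has eps = 0
#' for every sigma and the lambda sigma^2 term plus the smaller-sigma tie
#' rule selects the grid minimum.
#'
#' @param vec,weight as in [grey_3d()].
#' @param cfg a [pipeline_config()] (lambda, sigma grid).
#' @return list with `sigma` (per-voxel array) and `grid`.
#' @export
adaptive_sigma <- function(vec, weight, cfg = pipeline_config()) {
  grid <- seq(cfg$sigma_min, cfg$sigma_max, by = cfg$sigma_step)
  d <- dim(weight)
  Vw <- lapply(1:3, function(i) {
    a <- double_angle_3d(vec, i)
    for (k in 1:3) a[, , , k] <- a[, , , k] * weight
    a
  })
  offs <- list(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  best_d <- array(Inf, d)
  best_s <- array(grid[1], d)
  for (s in grid) {
    eps2 <- array(0, d)
    for (i in 1:3) for (k in 1:3) {
      raw <- Vw[[i]][, , , k]
      sm <- gauss_smooth(raw, s)
      for (o in offs)   # smoothed value at q = p + o, compared to raw at p
        eps2 <- eps2 + (shift_arr3(sm, -o[1], -o[2], -o[3]) - raw)^2
    }
    dd <- cfg$lambda_sigma * s^2 + eps2
    upd <- dd < best_d - 1e-12
    best_d[upd] <- dd[upd]
    best_s[upd] <- s
  }
  list(sigma = best_s, grid = grid)
}

#' Segment an assigned, weighted volume in 3-D
#'
#' Adaptive (or fixed) Gaussian scale, anisotropy volume, then watershed with
#' merging at threshold `f_min_3d`. Voxels with zero weight are masked.
#'
#' @param vol volume with `vec` and `weight` (e.g. after [voxel_weights()],
#'   or a phantom).
#' @param cfg a [pipeline_config()].
#' @param adaptive use per-voxel adaptive sigma (default) or fixed `sigma`.
#' @param sigma fixed sigma when `adaptive = FALSE`.
#' @return list with `labels` (pool labels, -1 watershed, 0 masked),
#'   `edges` (logical), `cache`, `sigma`.
#' @export
segment_3d <- function(vol, cfg = pipeline_config(), adaptive = TRUE, sigma = 1) {
  w <- vol$weight
  if (adaptive) {
    as_ <- adaptive_sigma(vol$vec, w, cfg)
    cache <- grey_3d(vol$vec, w, sigma = as_$sigma, sigma_grid = as_$grid)
    sig <- as_$sigma
  } else {
    cache <- grey_3d(vol$vec, w, sigma = sigma)
    sig <- sigma
  }
  lab <- watershed_merge(cache$I_w, mask = w > 0,
                         f = function(p, q) merge_f_3d(p, q, cache),
                         f_min = cfg$f_min_3d)
  list(labels = lab, edges = lab == -1L, cache = cache, sigma = sig)
}

## ---- brute-force oracles (used by tests and documented for verification) --

#' Brute-force weighted anisotropy at a point (double sum)
#'
#' Direct evaluation of `sum_jk g_j g_k w_j w_k (c (v_j . v_k)^2 - 1)` with
#' c = 2 in 2-D and 4 in 3-D, over the kernel window with zero padding.
#' Quadratic cost; exists to pin the closed forms down to 1e-9.
#'
#' @param vecs n x 2 or n x 3 matrix of window vectors (rows; zero rows =
#'   empty).
#' @param w weights (length n). @param g kernel values (length n).
#' @param c_factor 2 or 4.
#' @return scalar.
#' @export
brute_anisotropy <- function(vecs, w, g, c_factor = 2) {
  gw <- g * w
  G <- outer(gw, gw)
  VV <- vecs %*% t(vecs)
  sum(G * (c_factor * VV^2 - 1))
}

#' Brute-force pool comparison (double sum)
#'
#' `sum_jk g_j g_k w_p(j) w_q(k) (v_j . u_k)^2 / sum_nm g_n g_m w_p(n)
#' w_q(m)`.
#'
#' @param vp,vq window vectors around p and q. @param wp,wq weights.
#' @param g kernel values.
#' @return scalar in `[0, 1]`.
#' @export
brute_f <- function(vp, wp, vq, wq, g) {
  num <- sum(outer(g * wp, g * wq) * (vp %*% t(vq))^2)
  den <- sum(g * wp) * sum(g * wq)
  num / den
}
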