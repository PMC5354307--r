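## Final smoothing, width morphometry and verification statistics: boundary-respecting smoothing,
## bundle-width sampling, and the equivalence tests comparing registered and
## unregistered width distributions.

#' Final direction smoothing with edges and masks excluded
#'
#' Removes edge / vessel / placenta voxels, multiplies the remaining unit
#' vectors by their weights, and convolves with a radius-1 Gaussian whose
#' stencil skips excluded voxels (boundaries never bleed). Vectors are
#' headless: each neighbour is flipped into the hemisphere of the centre
#' vector before summing, so the output is invariant to sign flips of the
#' input. Output direction = normalised smoothed vector; weight = its length.
#'
#' @param vol volume with `vec`, `weight`.
#' @param edges logical array of segmentation edges (or NULL).
#' @param vessel_mask,placenta_mask logical arrays (or NULL).
#' @param radius stencil radius in voxels.
#' @param sigma Gaussian sd for the stencil (default 1).
#' @return volume with smoothed `vec` and `weight` (excluded voxels zeroed),
#'   plus `excluded` array.
#' @export
final_smooth <- function(vol, edges = NULL, vessel_mask = NULL,
                         placenta_mask = NULL, radius = 1L, sigma = 1) {
  d <- dim(vol$weight)
  excl <- array(FALSE, d)
  for (m in list(edges, vessel_mask, placenta_mask)) if (!is.null(m)) excl <- excl | m
  ok <- vol$weight > 0 & !excl
  k1 <- gauss_kernel(sigma, radius)
  wvec <- array(0, c(d, 3))
  for (k in 1:3) wvec[, , , k] <- vol$vec[, , , k] * vol$weight * ok
  sx <- array(0, d); sy <- array(0, d); sz <- array(0, d); norm <- array(0, d)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  cx <- vol$vec[, , , 1]; cy <- vol$vec[, , , 2]; cz <- vol$vec[, , , 3]
  for (r in seq_len(nrow(offs))) {
    g <- k1[offs$dx[r] + radius + 1] * k1[offs$dy[r] + radius + 1] *
      k1[offs$dz[r] + radius + 1]
    nx_ <- shift_arr3(wvec[, , , 1], offs$dx[r], offs$dy[r], offs$dz[r])
    ny_ <- shift_arr3(wvec[, , , 2], offs$dx[r], offs$dy[r], offs$dz[r])
    nz_ <- shift_arr3(wvec[, , , 3], offs$dx[r], offs$dy[r], offs$dz[r])
    inc <- shift_arr3(ok * 1, offs$dx[r], offs$dy[r], offs$dz[r])
    ## headless alignment: flip the neighbour into the centre's hemisphere
    sgn <- sign(cx * nx_ + cy * ny_ + cz * nz_)
    sgn[sgn == 0] <- 1
    sx <- sx + g * sgn * nx_
    sy <- sy + g * sgn * ny_
    sz <- sz + g * sgn * nz_
    norm <- norm + g * inc
  }
  len <- sqrt(sx^2 + sy^2 + sz^2)
  wt <- ifelse(norm > 0, len / norm, 0)  # renormalised: uniform field unchanged
  wt[!ok] <- 0
  vec <- array(0, c(d, 3))
  safe <- len > 1e-12 & ok
  for (k in 1:3) {
    comp <- list(sx, sy, sz)[[k]]
    v <- array(0, d)
    v[safe] <- comp[safe] / len[safe]
    vec[, , , k] <- v
  }
  out <- vol
  out$vec <- vec
  out$weight <- wt
  out$excluded <- excl
  out
}

#' 2-D final smoothing of a segmented slide
#'
#' Removes edge (and projected mask) pixels and smooths the remaining planar
#' double-angle field with a radius-1 Gaussian; used before 2-D width
#' measurement on registered and unregistered slides.
#'
#' @param slide a [regional_slide()].
#' @param edges logical matrix of removed points.
#' @param sigma,radius stencil parameters.
#' @return list with `planar` (logical), `theta` (smoothed angles).
#' @export
final_smooth_2d <- function(slide, edges = NULL, sigma = 1, radius = 1L) {
  d <- dim(slide$category)
  if (is.null(edges)) edges <- matrix(FALSE, d[1], d[2])
  ok <- slide$category == CAT_PLANAR & !edges
  th0 <- ifelse(ok, slide$theta, 0)
  cx <- cospi(th0 / 90) * ok; sx <- sinpi(th0 / 90) * ok
  k1 <- gauss_kernel(sigma, radius)
  ax <- matrix(0, d[1], d[2]); ay <- matrix(0, d[1], d[2])
  for (dx in -radius:radius) for (dy in -radius:radius) {
    g <- k1[dx + radius + 1] * k1[dy + radius + 1]
    ax <- ax + g * shift_mat(cx, dx, dy)
    ay <- ay + g * shift_mat(sx, dx, dy)
  }
  theta <- ang_norm180(atan2(ay, ax) * 90 / pi)
  theta[!ok] <- NA_real_
  list(planar = ok, theta = theta)
}

## Step along +-dir from a start point in 0.5-unit steps until the containing
## cell fails `inside(p)`. The segment between the two first-failing points
## overshoots the tissue by up to one step per side (half a step on average),
## so the width is that distance minus one full step - unbiased against the
## continuous segment length and exact for axis-aligned slabs.
trace_width <- function(start, dir, inside, step = 0.5, max_steps = 4000L) {
  run <- function(sgn) {
    for (i in seq_len(max_steps)) {
      p <- start + sgn * i * step * dir
      if (!inside(p)) return(i * step)
    }
    max_steps * step
  }
  run(1) + run(-1) - step
}

#' Sample bundle widths on a random-offset grid
#'
#' 2-D: nodes on a uniform grid (pitch `width_grid_regions` regions, random
#' offset); at planar pixels the width is the length of the segment through
#' the node, perpendicular to the local direction, staying in planar tissue.
#' 3-D: lattice with the same in-plane pitch and 1-voxel z pitch; the width
#' direction is drawn uniformly from the great circle perpendicular to the
#' voxel direction; voxels with weight below `weight_min` do not count as
#' tissue.
#'
#' @param domain `"slide2d"` or `"volume3d"`.
#' @param field for 2-D: result of [final_smooth_2d()]; for 3-D: a smoothed
#'   volume with `vec` and `weight`.
#' @param pitch_um physical pitch of a region/voxel, um.
#' @param cfg a [pipeline_config()].
#' @param seed RNG seed for the grid offset and direction draws.
#' @return data.frame of samples: `x, y, z` (node, 0-based), `dx, dy, dz`
#'   (width direction), `width_um`.
#' @export
measure_widths <- function(domain = c("slide2d", "volume3d"), field, pitch_um,
                           cfg = pipeline_config(), seed = cfg$seed) {
  domain <- match.arg(domain)
  set.seed(seed)
  gp <- cfg$width_grid_regions
  if (domain == "slide2d") {
    d <- dim(field$planar)
    off <- stats::runif(2, 0, gp)
    xs <- seq(ceiling(off[1]), d[1] - 1, by = gp)
    ys <- seq(ceiling(off[2]), d[2] - 1, by = gp)
    inside <- function(p) {
      i <- floor(p[1] + 0.5) + 1; j <- floor(p[2] + 0.5) + 1
      i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && field$planar[i, j]
    }
    out <- list()
    for (x in xs) for (y in ys) {
      if (!field$planar[x + 1, y + 1]) next
      th <- field$theta[x + 1, y + 1]
      dir <- c(-sinpi(th / 180), cospi(th / 180))  # perpendicular to theta
      w <- trace_width(c(x, y), dir, inside)
      out[[length(out) + 1L]] <- data.frame(x = x, y = y, z = 0,
                                            dx = dir[1], dy = dir[2], dz = 0,
                                            width_um = w * pitch_um)
    }
  } else {
    d <- dim(field$weight)
    off <- stats::runif(3, 0, c(gp, gp, 1))
    xs <- seq(ceiling(off[1]), d[1] - 1, by = gp)
    ys <- seq(ceiling(off[2]), d[2] - 1, by = gp)
    zs <- seq(ceiling(off[3]), d[3] - 1, by = 1)
    inside <- function(p) {
      i <- floor(p[1] + 0.5) + 1; j <- floor(p[2] + 0.5) + 1; k <- floor(p[3] + 0.5) + 1
      i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3] &&
        field$weight[i, j, k] > cfg$weight_min
    }
    out <- list()
    for (x in xs) for (y in ys) for (z in zs) {
      if (field$weight[x + 1, y + 1, z + 1] <= cfg$weight_min) next
      v <- field$vec[x + 1, y + 1, z + 1, ]
      ## orthonormal basis of the perpendicular plane
      a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * v) * v; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(v[2] * e1[3] - v[3] * e1[2], v[3] * e1[1] - v[1] * e1[3],
              v[1] * e1[2] - v[2] * e1[1])
      alpha <- stats::runif(1, 0, 2 * pi)
      dir <- cos(alpha) * e1 + sin(alpha) * e2
      w <- trace_width(c(x, y, z), dir, inside)
      out[[length(out) + 1L]] <- data.frame(x = x, y = y, z = z, dx = dir[1],
                                            dy = dir[2], dz = dir[3],
                                            width_um = w * pitch_um)
    }
  }
  if (!length(out)) stop("no samples: the grid hit no tissue")
  do.call(rbind, out)
}

#' Equivalence statistics between two width distributions
#'
#' Mean equivalence: Welch 95% CI of the difference of log-width means must
#' lie inside the 5%-deformation interval `(log(1/1.05), log(1/0.95)) =
#' (-0.0488, 0.0513)`. Distribution equivalence: repeated 1000-value
#' subsamples from each set give the bootstrap distribution of the normalised
#' Kolmogorov-Smirnov statistic `sqrt(nm/(n+m)) * sup|F_u - F_r|`; the
#' distributions are deemed equivalent when `P(K < 1.36)` is at least 0.90.
#' The verdict is `"equivalent"` only if both tests pass.
#'
#' @param widths_u,widths_r width samples (um), unregistered and registered;
#'   each needs at least `ks_subsample` values.
#' @param cfg a [pipeline_config()].
#' @param seed RNG seed for the bootstrap.
#' @return list: `mean_log_diff`, `ci95`, `effect_interval`, `mean_equiv`,
#'   `ks_stats` (bootstrap sample), `ks_prob`, `ks_ci90`, `dist_equiv`,
#'   `verdict`.
#' @export
equivalence_stats <- function(widths_u, widths_r, cfg = pipeline_config(),
                              seed = cfg$seed) {
  n <- cfg$ks_subsample
  if (length(widths_u) < n || length(widths_r) < n)
    stop("need at least ", n, " width values per sample")
  lu <- log(widths_u); lr <- log(widths_r)
  tt <- stats::t.test(lu, lr, conf.level = 0.95)  # Welch
  ci <- unname(tt$conf.int)
  eff <- cfg$effect_interval
  mean_equiv <- ci[1] > eff[1] && ci[2] < eff[2]
  set.seed(seed)
  ks <- vapply(seq_len(cfg$ks_reps), function(i) {
    su <- sample(widths_u, n, replace = FALSE)
    sr <- sample(widths_r, n, replace = FALSE)
    d <- ks_statistic(su, sr)
    sqrt(n * n / (n + n)) * d
  }, numeric(1))
  prob <- mean(ks < cfg$ks_critical)
  ci90 <- unname(stats::quantile(ks, c(0.05, 0.95)))
  dist_equiv <- prob >= cfg$ks_prob_min
  list(mean_log_diff = unname(tt$estimate[1] - tt$estimate[2]), ci95 = ci,
       effect_interval = eff, mean_equiv = mean_equiv,
       ks_stats = ks, ks_prob = prob, ks_ci90 = ci90, dist_equiv = dist_equiv,
       verdict = if (mean_equiv && dist_equiv) "equivalent" else "not_equivalent")
}

#' Two-sample Kolmogorov-Smirnov statistic `sup |F1 - F2|`
#' @param x,y numeric samples.
#' @return the unnormalised supremum distance.
#' @export
ks_statistic <- function(x, y) {
  n <- length(x); m <- length(y)
  z <- c(sort(x), sort(y))
  o <- order(z, c(rep(1L, n), rep(2L, m)))
  steps <- ifelse(c(rep(1L, n), rep(2L, m))[o] == 1L, 1 / n, -1 / m)
  max(abs(cumsum(steps)))
}

#' Width maps over the sampling lattice
#'
#' Median width along z per (x, y) lattice cell, and median per z slice,
#' each with 95% CIs from the binomial order-statistic method.
#'
#' @param samples data.frame from [measure_widths()].
#' @return list with `xy_map` (data.frame x, y, median, n) and `z_profile`
#'   (data.frame z, median, lo, hi, n).
#' @export
width_maps <- function(samples) {
  med_ci <- function(w) {
    w <- sort(w); n <- length(w)
    if (n == 0L) return(c(NA, NA, NA))
    lo <- stats::qbinom(0.025, n, 0.5); hi <- stats::qbinom(0.975, n, 0.5) + 1L
    c(stats::median(w), w[max(1L, lo)], w[min(n, hi)])
  }
  xy <- stats::aggregate(width_um ~ x + y, data = samples, FUN = stats::median)
  names(xy)[3] <- "median_um"
  xy$n <- stats::aggregate(width_um ~ x + y, data = samples, FUN = length)$width_um
  zs <- sort(unique(samples$z))
  zp <- do.call(rbind, lapply(zs, function(z) {
    m <- med_ci(samples$width_um[samples$z == z])
    data.frame(z = z, median_um = m[1], lo = m[2], hi = m[3],
               n = sum(samples$z == z))
  }))
  list(xy_map = xy, z_profile = zp)
}
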