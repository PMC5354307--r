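## Shared synthetic builders. Everything is generated in code at test time;
## results are memoised per session because several files reuse the same
## slides.

.fix_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fix_env)) assign(key, force(expr), .fix_env)
  get(key, .fix_env)
}

## Quasi-random blockwise bundle field: 8-px bundles with strong angular
## contrast between neighbours and 2-px gaps (what the elastic energy needs).
block_field <- function(x, y) c((137.508 * (floor(x / 8) * 13 + floor(y / 8) * 7)) %% 180, 0)
block_mask <- function(x, y) (x %% 8 > 1) & (y %% 8 > 1)

## Asymmetric tissue disc (ellipse with a notch) for rigid registration.
notched_mask <- function(cx, cy, a2, b2) {
  function(x, y) ((x - cx)^2 / a2 + (y - cy)^2 / b2) < 1 & !(x > cx & y > cy + 10)
}

## A block-pattern slide: ellipse table + regional slide on an
## nx x nx content grid inside a frame_w x frame_w frame.
block_slide <- function(nx = 96, frame = 96, b0 = 8, seed = 2) {
  memo(sprintf("block_%d_%d_%d_%d", nx, frame, b0, seed), {
    cfg <- pipeline_config(resolution = resolution_config(frame_w = frame, frame_h = frame),
                           b0 = b0)
    spec <- phantom_spec(field = block_field, nuclear_density = 8, angle_noise_sd = 3,
                         bundle_mask = block_mask, seed = seed)
    e <- synth_ellipses(spec, nx, nx, cfg)
    rs <- pad_and_grid(e, cfg, slide_number = 1)
    rp <- cfg$resolution$region_px
    off <- attr(rs, "offset_regions")
    e$rx <- e$cx / rp + off[1]
    e$ry <- e$cy / rp + off[2]
    list(cfg = cfg, ellipses = e, regional = rs)
  })
}

## Edge image of a notched tissue disc (rigid registration shape).
disc_edges <- function(frame = 96, seed = 5) {
  memo(sprintf("disc_%d_%d", frame, seed), {
    cfg <- pipeline_config(resolution = resolution_config(frame_w = frame, frame_h = frame))
    c0 <- frame / 2
    spec <- phantom_spec(field = c(30, 0), nuclear_density = 8,
                         bundle_mask = notched_mask(c0, c0, 1400, 800), seed = seed)
    e <- synth_ellipses(spec, frame, frame, cfg)
    rs <- pad_and_grid(e, cfg, slide_number = 1)
    list(cfg = cfg, regional = rs, points = edge_image(rs, cfg)$points,
         dims = c(frame, frame))
  })
}

## Random weighted 2-D regional slide for the identity oracles.
random_slide_7x7 <- function() {
  W <- 7; H <- 7
  cat <- matrix(sample(0:2, W * H, TRUE, prob = c(.2, .6, .2)), W, H)
  th <- matrix(runif(W * H, 0, 180), W, H); th[cat != 1] <- NA
  cnt <- matrix(rpois(W * H, 4), W, H) * (cat != 0)
  regional_slide(cat, th, cnt)
}

## Random weighted 3-D vector volume (unit vectors where weight > 0).
random_volume_5 <- function() {
  d <- c(5, 5, 5)
  w <- array(rpois(125, 2) * rbinom(125, 1, .8), d)
  v <- array(rnorm(375), c(d, 3))
  n <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  for (k in 1:3) v[, , , k] <- v[, , , k] / n
  for (k in 1:3) { vk <- v[, , , k]; vk[w == 0] <- 0; v[, , , k] <- vk }
  list(v = v, w = w)
}

## Extract the kernel window (vectors, weights, kernel values) around a
## linear index, zero-padded - the independent double-sum oracle's view.
win2d <- function(slide, p, sigma = 1, rad = 3) {
  K <- myovol:::gauss_kernel_nd(sigma, 2, rad)
  d <- dim(slide$category)
  px <- (p - 1) %% d[1] + 1; py <- (p - 1) %/% d[1] + 1
  vs <- NULL; ws <- NULL; gs <- NULL
  for (dy in -rad:rad) for (dx in -rad:rad) {
    x <- px + dx; y <- py + dy
    v <- c(0, 0); w <- 0
    if (x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && slide$category[x, y] == 1) {
      v <- c(cospi(slide$theta[x, y] / 180), sinpi(slide$theta[x, y] / 180))
      w <- slide$count[x, y]
    }
    vs <- rbind(vs, v); ws <- c(ws, w); gs <- c(gs, K[dx + rad + 1, dy + rad + 1])
  }
  list(v = vs, w = ws, g = gs)
}

win3d <- function(rv, p, sigma = 1, rad = 3) {
  K <- myovol:::gauss_kernel_nd(sigma, 3, rad)
  d <- dim(rv$w)
  pz <- (p - 1) %/% (d[1] * d[2]) + 1
  r <- (p - 1) %% (d[1] * d[2])
  py <- r %/% d[1] + 1; px <- r %% d[1] + 1
  vs <- NULL; ws <- NULL; gs <- NULL
  for (dz in -rad:rad) for (dy in -rad:rad) for (dx in -rad:rad) {
    x <- px + dx; y <- py + dy; z <- pz + dz
    v <- c(0, 0, 0); w <- 0
    if (x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3] &&
        rv$w[x, y, z] > 0) {
      v <- rv$v[x, y, z, ]; w <- rv$w[x, y, z]
    }
    vs <- rbind(vs, v); ws <- c(ws, w)
    gs <- c(gs, K[dx + rad + 1, dy + rad + 1, dz + rad + 1])
  }
  list(v = vs, w = ws, g = gs)
}

## Pure-R reference walk for the boundary-distance probe (independent of the C++
## implementation): only used on phantoms whose voxels are planar/vertical
## with no pre-assigned vectors.
r_line_length <- function(vol, p0, v, L_max = 40) {
  v <- v / sqrt(sum(v^2))
  d <- dim(vol$category)
  dl <- min(1 / abs(v[abs(v) > 1e-9]))
  phi_v <- asin(max(-1, min(1, v[3]))) * 180 / pi
  th_v <- (atan2(v[2], v[1]) * 180 / pi) %% 360
  getcat <- function(q) {
    if (any(q < 0) || any(q >= d)) return(-1L)
    vol$category[q[1] + 1, q[2] + 1, q[3] + 1]
  }
  gettheta <- function(q) vol$theta[q[1] + 1, q[2] + 1, q[3] + 1]
  tempu <- function(q, tv) {
    cc <- getcat(q)
    if (cc == 1) {
      t1 <- gettheta(q)
      if (min(abs(t1 - tv) %% 360, 360 - abs(t1 - tv) %% 360) > 90) t1 <- (t1 + 180) %% 360
      c(t1, phi_v)
    } else c(tv, phi_v)
  }
  ok_next <- function(u, q) {
    cc <- getcat(q)
    if (cc <= 0) return(FALSE)
    if (cc == 1) {
      dd <- abs(gettheta(q) - u[1]) %% 180
      return(min(dd, 180 - dd) < 30)
    }
    abs(u[2]) > 30
  }
  u0 <- tempu(p0, th_v)
  u <- list(u0, u0)
  prev <- list(p0, p0)
  for (i in 1:L_max) {
    for (arm in 1:2) {
      sgn <- c(1, -1)[arm]
      q <- round(p0 + sgn * i * dl * v)
      if (all(q == prev[[arm]])) next
      if (!ok_next(u[[arm]], q)) return(i)
      u[[arm]] <- tempu(q, th_v)
      prev[[arm]] <- q
    }
  }
  L_max
}
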