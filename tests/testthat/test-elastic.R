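test_that("heterogeneity matches its closed-form cases and threshold", {
  cfg <- pipeline_config()
  expect_equal(cfg$het_min_deg2, 45^2)
  expect_equal(as.numeric(heterogeneity(rep(1L, 12), rep(33, 12))), 0)
  ## half planar at the mean, half non-planar (filled at mean + 90):
  ## 50/50 headless two-point distribution 90 degrees apart
  h <- heterogeneity(c(rep(1L, 6), rep(0L, 6)), c(rep(20, 6), rep(NA, 6)))
  expect_equal(as.numeric(h), 2025, tolerance = 1e-6)
  ## no planar pixels -> 0 with degenerate flag
  h0 <- heterogeneity(rep(0L, 4), rep(NA_real_, 4))
  expect_equal(as.numeric(h0), 0)
  expect_true(isTRUE(attr(h0, "degenerate")))
})

test_that("match energy is 0 on self, 1 under an over-rotated field", {
  cfg <- pipeline_config()
  sl <- block_slide(nx = 48, frame = 48)
  area <- myovol:::tile_area(sl$regional, 2, 2, cfg)
  px <- myovol:::area_pixels(sl$regional, area)
  expect_equal(match_energy(px, sl$regional, 0, c(0, 0), cfg), 0)
  ## uniformly planar area whose angles all differ by 25 > a_max from the
  ## reference: no pixel can match
  cat <- matrix(1L, 20, 20)
  ref <- regional_slide(cat, theta = matrix(40, 20, 20), count = cat * 4)
  mov <- regional_slide(cat, theta = matrix(65, 20, 20), count = cat * 4)
  pxm <- myovol:::area_pixels(mov, list(x0 = 3, x1 = 18, y0 = 3, y1 = 18))
  expect_equal(match_energy(pxm, ref, 0, c(0, 0), cfg), 1)
  ## elastic parameter defaults
  expect_equal(cfg$a_max, 20)
  expect_equal(cfg$e_min, 0.2)
  expect_equal(pipeline_config(b0 = 16)$b0, 16)  # rat value; human default 32
})

test_that("the translation bound scales with the identity energy", {
  ## b(A) = b0 * e(A, T0): e = 0.5 with b0 = 16 bounds |t| by 8
  expect_equal(16 * 0.5, 8)
  cfg <- pipeline_config(b0 = 16)
  sl <- block_slide(nx = 48, frame = 48, b0 = 16)
  ## displaced copy of the slide: recovered translation within 1 px
  e2 <- sl$ellipses
  e2$rx <- e2$rx + 5; e2$ry <- e2$ry + 3
  mov <- myovol:::regrid_regional(e2, sl$regional, cfg)
  tr <- register_tile(mov, sl$regional, 2, 2, cfg)
  expect_equal(tr$flag, "hough")
  expect_lte(max(abs(tr$t - c(-5, -3))), 1)
  expect_lte(abs(tr$theta), 2)
  ## a tile that already matches is left untested (identity)
  tr0 <- register_tile(sl$regional, sl$regional, 2, 2, cfg)
  expect_equal(tr0$flag, "identity")
  expect_equal(tr0$t, c(0, 0))
})

test_that("warp blending is exact in its limit cases", {
  ## all-identity tiles -> exact identity map
  tiles <- replicate(9, list(theta = 0, t = c(0, 0)), simplify = FALSE)
  dim(tiles) <- c(3, 3)
  reg <- list(tiles = tiles, centres_x = c(7.5, 23.5, 39.5),
              centres_y = c(7.5, 23.5, 39.5), ntx = 3, nty = 3, tile_px = 16)
  p <- cbind(runif(20, 0, 47), runif(20, 0, 47))
  expect_equal(apply_warp(p, reg), p)
  ## point on a tile centre takes that tile's transform exactly
  reg2 <- reg
  reg2$tiles[[1, 1]]$t <- c(4, 0)
  expect_equal(apply_warp(matrix(c(7.5, 7.5), 1), reg2)[1, ], c(11.5, 7.5))
  ## equidistant point averages the four translations
  reg3 <- reg
  reg3$tiles[[1, 1]]$t <- c(1, 0); reg3$tiles[[2, 1]]$t <- c(3, 0)
  reg3$tiles[[1, 2]]$t <- c(1, 0); reg3$tiles[[2, 2]]$t <- c(3, 0)
  mid <- c(mean(c(7.5, 23.5)), mean(c(7.5, 23.5)))
  expect_equal(apply_warp(matrix(mid, 1), reg3)[1, ], mid + c(2, 0))
})

test_that("warp field is continuous across tile boundaries", {
  set.seed(6)
  tiles <- replicate(9, list(theta = runif(1, -3, 3),
                             t = runif(2, -2, 2)), simplify = FALSE)
  dim(tiles) <- c(3, 3)
  reg <- list(tiles = tiles, centres_x = c(7.5, 23.5, 39.5),
              centres_y = c(7.5, 23.5, 39.5), ntx = 3, nty = 3, tile_px = 16)
  ## crossing x = 16 (tile boundary): displacement varies continuously
  xs <- seq(15.5, 16.5, by = 0.05)
  p <- cbind(xs, 20)
  w <- apply_warp(p, reg)
  step_sizes <- sqrt(rowSums(diff(w)^2))
  expect_lt(max(step_sizes), 0.2)
})

test_that("neighbourhood refinement never increases the neighbourhood energy", {
  cfg <- pipeline_config(b0 = 8)
  sl <- block_slide(nx = 48, frame = 48, b0 = 8)
  d <- distort_stack(list(sl$ellipses), elastic_amplitude = 4 * 128,
                     extent_px = c(48, 48) * 128, seed = 31)
  e2 <- d$slides[[1]]
  off <- attr(sl$regional, "offset_regions")
  e2$rx <- e2$cx / 128 + off[1]; e2$ry <- e2$cy / 128 + off[2]
  mov <- myovol:::regrid_regional(e2, sl$regional, cfg)
  ## compare pre-refinement tiles with refined assignment
  tp <- cfg$tile_px
  raw <- list()
  for (ty in 1:3) for (tx in 1:3)
    raw[[paste(tx, ty)]] <- register_tile(mov, sl$regional, tx, ty, cfg)
  reg <- elastic_register_slide(mov, sl$regional, cfg)
  for (ty in 1:3) for (tx in 1:3) {
    nbx <- max(1, tx - 1):min(3, tx + 1); nby <- max(1, ty - 1):min(3, ty + 1)
    nb_energy <- function(tr) {
      s <- 0
      for (j in nby) for (i in nbx) {
        a <- raw[[paste(i, j)]]$area
        if (is.null(a)) next
        pxs <- myovol:::area_pixels(mov, a)
        s <- s + match_energy(pxs, sl$regional, tr$theta, tr$t, cfg)
      }
      s
    }
    expect_lte(nb_energy(reg$tiles[[tx, ty]]), nb_energy(raw[[paste(tx, ty)]]) + 1e-9)
  }
})

test_that("match score is 0 for identical and 1 for disjoint slides", {
  cat1 <- matrix(0L, 20, 20); cat1[2:8, 2:8] <- 1L
  cat2 <- matrix(0L, 20, 20); cat2[12:18, 12:18] <- 1L
  s1 <- regional_slide(cat1, theta = matrix(10, 20, 20), count = cat1 * 4)
  s2 <- regional_slide(cat2, theta = matrix(10, 20, 20), count = cat2 * 4)
  expect_equal(match_score(s1, s1), 0)
  expect_equal(match_score(s1, s2), 1)
})

test_that("ordering picks a central reference in an identical stack with no discards", {
  cfg <- pipeline_config(resolution = resolution_config(frame_w = 48, frame_h = 48),
                         b0 = 8, substack_len = 5, ref_spacing = 2)
  sl <- block_slide(nx = 48, frame = 48, b0 = 8)
  stack <- replicate(7, list(ellipses = sl$ellipses, regional = sl$regional),
                     simplify = FALSE)
  out <- order_and_register(stack, cfg)
  expect_false(any(out$discard))
  ## all pairwise scores tie at 0 -> middle of the densest substack
  expect_equal(out$reference, 3)
  expect_error(order_and_register(stack[1:2], cfg), "at least 3")
})

test_that("seeded smooth warps are reduced below one region pixel", {
  cfg <- pipeline_config(resolution = resolution_config(frame_w = 96, frame_h = 96),
                         b0 = 8)
  sl <- block_slide(nx = 96, frame = 96, b0 = 8)
  rp <- 128
  off <- attr(sl$regional, "offset_regions")
  d <- distort_stack(list(sl$ellipses), elastic_amplitude = 4 * rp,
                     extent_px = c(96, 96) * rp, seed = 9)
  e3 <- d$slides[[1]]
  e3$rx <- e3$cx / rp + off[1]; e3$ry <- e3$cy / rp + off[2]
  mov <- myovol:::regrid_regional(e3, sl$regional, cfg)
  reg <- elastic_register_slide(mov, sl$regional, cfg)
  p <- apply_warp(cbind(e3$rx, e3$ry), reg)
  res <- sqrt(rowSums((p - cbind(sl$ellipses$rx, sl$ellipses$ry))^2))
  expect_lte(stats::median(res), 1)
})
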