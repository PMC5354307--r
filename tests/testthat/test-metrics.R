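test_that("final smoothing leaves uniform fields unchanged and respects edges", {
  d <- c(14, 14, 10)
  vec <- array(0, c(d, 3)); vec[, , , 1] <- 1
  vol <- list(vec = vec, weight = array(1, d))
  sm <- final_smooth(vol)
  expect_equal(sm$vec, vec, tolerance = 1e-12)
  expect_equal(sm$weight, vol$weight, tolerance = 1e-12)
  ## two-layer: no bleed across the excluded edge plane
  ph <- phantom_volume("two_layer", dims = c(16, 16, 16), bundle_width_vox = 5)
  edges <- array(FALSE, dim(ph$weight))
  edges[, , 9] <- ph$weight[, , 9] > 0   # the interface plane (layer 2 start)
  smp <- final_smooth(list(vec = ph$vec, weight = ph$weight), edges = edges)
  ## voxels adjacent to the edge keep their layer direction within 1 degree
  v1 <- smp$vec[8, 8, 8, ]
  expect_lt(acos(min(1, abs(sum(v1 * c(1, 0, 0))))) * 180 / pi, 1)
  v2 <- smp$vec[8, 8, 10, ]
  expect_lt(acos(min(1, abs(sum(v2 * c(0, 1, 0))))) * 180 / pi, 1)
  expect_true(all(smp$weight[edges] == 0))
})

test_that("smoothing output is invariant to headless sign flips of the input", {
  set.seed(19)
  d <- c(8, 8, 8)
  vec <- array(rnorm(prod(d) * 3), c(d, 3))
  n <- sqrt(vec[, , , 1]^2 + vec[, , , 2]^2 + vec[, , , 3]^2)
  for (k in 1:3) vec[, , , k] <- vec[, , , k] / n
  w <- array(runif(prod(d)), d)
  s1 <- final_smooth(list(vec = vec, weight = w))
  flip <- array(sample(c(-1, 1), prod(d), TRUE), d)
  vec2 <- vec
  for (k in 1:3) vec2[, , , k] <- vec2[, , , k] * flip
  s2 <- final_smooth(list(vec = vec2, weight = w))
  ## directions agree up to sign
  dot <- abs(s1$vec[, , , 1] * s2$vec[, , , 1] + s1$vec[, , , 2] * s2$vec[, , , 2] +
               s1$vec[, , , 3] * s2$vec[, , , 3])
  expect_true(all(abs(dot[w > 0] - 1) < 1e-9))
  expect_equal(s1$weight, s2$weight, tolerance = 1e-12)
})

test_that("2-D slab widths are exact and use the 4-region grid pitch", {
  cfg <- pipeline_config()
  expect_equal(cfg$width_grid_regions * 47.5, 190)   # grid pitch in um
  d <- c(40, 40)
  planar <- matrix(FALSE, d[1], d[2]); planar[, 11:20] <- TRUE
  theta <- matrix(NA_real_, d[1], d[2]); theta[, 11:20] <- 0
  w <- measure_widths("slide2d", list(planar = planar, theta = theta),
                      pitch_um = 47.5, cfg = cfg, seed = 4)
  expect_true(all(abs(w$width_um - 10 * 47.5) <= 47.5))
  expect_error(measure_widths("slide2d", list(planar = planar & FALSE, theta = theta),
                              47.5, cfg, seed = 1), "no samples")
})

test_that("3-D widths of a slab are exact and weights below 0.2 are excluded", {
  cfg <- pipeline_config(width_grid_regions = 2L)
  expect_equal(cfg$weight_min, 0.2)
  d <- c(20, 20, 16)
  vec <- array(0, c(d, 3)); vec[, , , 1] <- 1
  w <- array(0, d); w[, , 5:10] <- 1          # 6-voxel slab, fibres along x
  ## a low-weight lid must not count as tissue
  w[, , 11] <- 0.1
  samples <- measure_widths("volume3d", list(vec = vec, weight = w), pitch_um = 1,
                            cfg = cfg, seed = 7)
  ## widths perpendicular to x are chords of the (y, z) slab section: their
  ## z-projection cannot exceed the 6-voxel thickness, and chords that cross
  ## the full thickness away from the y-edges recover it within a voxel
  expect_true(all(samples$width_um * abs(samples$dz) <= 7))
  crossing <- abs(samples$dz) > 0.5 & samples$y > 4 & samples$y < 15
  expect_gt(sum(crossing), 0)
  expect_true(all(abs(samples$width_um[crossing] * abs(samples$dz[crossing]) - 6) <= 1.5))
  ## sampling is reproducible under a fixed seed
  s2 <- measure_widths("volume3d", list(vec = vec, weight = w), 1, cfg, seed = 7)
  expect_identical(samples, s2)
})

test_that("cylinder widths match the analytic chord oracle", {
  cy <- phantom_volume("cylinder", dims = c(30, 30, 40), bundle_width_vox = 24,
                       pitch_um = 1)
  cfgw <- pipeline_config(width_grid_regions = 1L)
  w3 <- measure_widths("volume3d", list(vec = cy$vec, weight = cy$weight), 1,
                       cfgw, seed = 5)
  expect_true(all(w3$width_um <= 24 + 2))
  ## independent oracle: analytic voxel membership + the documented 0.5-step
  ## sampling rule, same random design
  set.seed(77)
  r <- 12; step <- 0.5
  cen <- which(cy$weight[, , 1] > 0, arr.ind = TRUE) - 1
  N <- 8000
  i <- sample(nrow(cen), N, replace = TRUE)
  psi <- runif(N, 0, 2 * pi)
  member <- function(x, y) (round(x) - 14.5)^2 + (round(y) - 14.5)^2 <= r^2
  ow <- numeric(N)
  for (k in seq_len(N)) {
    p <- as.numeric(cen[i[k], 1:2]); dirv <- c(cos(psi[k]), sin(psi[k]))
    arm <- function(sgn) {
      j <- 1
      while (member(p[1] + sgn * j * step * dirv[1], p[2] + sgn * j * step * dirv[2]) &&
             j < 200) j <- j + 1
      j * step
    }
    ow[k] <- arm(1) + arm(-1) - step
  }
  kt <- suppressWarnings(stats::ks.test(sample(w3$width_um, 2000), ow))
  expect_gt(kt$p.value, 0.05)
})

test_that("equivalence statistics follow the 5% effect and bootstrap KS rules", {
  cfg <- pipeline_config()
  expect_equal(cfg$effect_interval, c(log(1) - log(1.05), log(1) - log(0.95)))
  expect_equal(round(cfg$effect_interval, 4), c(-0.0488, 0.0513))
  expect_equal(cfg$ks_critical, 1.36)
  set.seed(20)
  wu <- exp(rnorm(5000, log(450), 0.4))
  ## identical list: zero mean difference, equivalent
  es <- equivalence_stats(wu, wu, cfg, seed = 3)
  expect_equal(es$mean_log_diff, 0)
  expect_equal(es$verdict, "equivalent")
  ## 20% multiplicative shift: clearly not equivalent
  es2 <- equivalence_stats(wu, 1.2 * wu, cfg, seed = 3)
  expect_equal(es2$verdict, "not_equivalent")
  expect_false(es2$mean_equiv)
  expect_lt(abs(es2$mean_log_diff + log(1.2)), 0.05)
  expect_error(equivalence_stats(wu[1:100], wu, cfg), "at least")
  ## the hand-rolled KS statistic agrees with stats::ks.test
  x <- rnorm(300); y <- rnorm(280, 0.3)
  expect_equal(ks_statistic(x, y),
               unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
               tolerance = 1e-12)
})

test_that("width maps report medians per column and per z-slice", {
  s <- data.frame(x = rep(c(0, 4), each = 6), y = 0,
                  z = rep(0:5, 2), dx = 0, dy = 1, dz = 0,
                  width_um = c(rep(300, 6), rep(500, 6)))
  m <- width_maps(s)
  expect_equal(m$xy_map$median_um, c(300, 500))
  expect_equal(m$z_profile$median_um, rep(400, 6))
  expect_equal(stats::median(c(3, 5, 9)), 5)  # odd-count convention used
  ## two-layer phantom-style step in z
  s2 <- data.frame(x = 0, y = 0, z = rep(0:7, each = 5), dx = 0, dy = 0, dz = 1,
                   width_um = rep(c(6, 12) * 47.5, each = 20))
  m2 <- width_maps(s2)
  expect_equal(m2$z_profile$median_um[1], 6 * 47.5)
  expect_equal(m2$z_profile$median_um[8], 12 * 47.5)
})
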