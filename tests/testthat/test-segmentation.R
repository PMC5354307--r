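test_that("watershed flooding separates and merges pools by the comparison rule", {
  x <- seq(-3, 3, length.out = 32)
  one <- exp(-outer(x^2, x^2, "+"))
  w1 <- watershed_merge(one, f = 0, f_min = 0.5)
  expect_equal(max(w1), 1)
  expect_equal(sum(w1 == -1), 0)
  two <- exp(-outer((x + 1.5)^2, x^2, "+")) + exp(-outer((x - 1.5)^2, x^2, "+"))
  wsplit <- watershed_merge(two, f = 0, f_min = 0.5)
  expect_equal(max(wsplit), 2)
  expect_gt(sum(wsplit == -1), 0)
  ## the ridge is a closed line: no two labels touch by face without a
  ## watershed/masked point between them
  d <- dim(wsplit)
  for (sh in list(c(1, 0), c(0, 1))) {
    a <- wsplit[1:(d[1] - sh[1]), 1:(d[2] - sh[2])]
    b <- wsplit[(1 + sh[1]):d[1], (1 + sh[2]):d[2]]
    expect_false(any(a > 0 & b > 0 & a != b))
  }
  wmerge <- watershed_merge(two, f = 1, f_min = 0.5)
  expect_equal(max(wmerge), 1)
  expect_equal(sum(wmerge == -1), 0)
})

test_that("2-D grey images use the published parameters and mask empties", {
  cfg <- pipeline_config()
  expect_equal(cfg$seg2d_var, 1.0)
  expect_equal(cfg$vert_grey_min, 10.0)
  expect_equal(cfg$f_min_2d, 0.54)
  expect_equal(cfg$planar_grey_min, 0.01)
  empty <- regional_slide(matrix(0L, 20, 20))
  g <- grey_2d(empty, cfg)
  expect_false(any(g$vertical_edges))
  expect_false(any(g$mask))
  ## uniform planar field with unit counts: interior I_w is the constant
  ## (sum of kernel)^2 = 1
  cat <- matrix(1L, 30, 30)
  uni <- regional_slide(cat, theta = matrix(42, 30, 30), count = cat)
  gu <- grey_2d(uni, cfg)
  expect_equal(gu$I_w[15, 15], 1, tolerance = 1e-9)
})

test_that("2-D closed forms equal the brute-force double sums (random fields)", {
  set.seed(16)
  maxI <- 0; maxf <- 0
  for (rep in 1:30) {
    s <- random_slide_7x7()
    g <- grey_2d(s, pipeline_config())
    pts <- sample(49, 4)
    for (p in pts) {
      w <- win2d(s, p)
      maxI <- max(maxI, abs(brute_anisotropy(w$v, w$w, w$g, 2) - g$I_w[p]))
    }
    pq <- sample(49, 2)
    w1 <- win2d(s, pq[1]); w2 <- win2d(s, pq[2])
    if (sum(w1$w) > 0 && sum(w2$w) > 0)
      maxf <- max(maxf, abs(brute_f(w1$v, w1$w, w2$v, w2$w, w1$g) -
                              merge_f_2d(pq[1], pq[2], g)))
  }
  expect_lt(maxI, 1e-9)
  expect_lt(maxf, 1e-9)
})

test_that("2-D comparison is 1 for identical and 0 for perpendicular fields", {
  cfg <- pipeline_config()
  cat <- matrix(1L, 24, 24)
  th <- matrix(30, 24, 24); th[13:24, ] <- 120   # two perpendicular halves
  s <- regional_slide(cat, theta = th, count = cat * 3)
  g <- grey_2d(s, cfg)
  lin <- function(x, y) x + 24 * (y - 1)
  expect_equal(merge_f_2d(lin(6, 12), lin(6, 13), g), 1, tolerance = 1e-9)
  expect_equal(merge_f_2d(lin(6, 12), lin(20, 12), g), 0, tolerance = 1e-9)
  ## empty tissue cannot merge
  s0 <- regional_slide(matrix(0L, 24, 24))
  g0 <- grey_2d(s0, cfg)
  expect_equal(merge_f_2d(1, 2, g0), 0)
})

test_that("3-D closed forms equal the brute-force double sums (random volumes)", {
  set.seed(17)
  maxI <- 0; maxf <- 0
  for (rep in 1:20) {
    rv <- random_volume_5()
    g <- grey_3d(rv$v, rv$w, sigma = 1)
    for (p in sample(which(rv$w > 0), 3)) {
      w <- win3d(rv, p)
      maxI <- max(maxI, abs(brute_anisotropy(w$v, w$w, w$g, 2) - g$I_w[p]))
    }
    pq <- sample(which(rv$w > 0), 2)
    w1 <- win3d(rv, pq[1]); w2 <- win3d(rv, pq[2])
    maxf <- max(maxf, abs(brute_f(w1$v, w1$w, w2$v, w2$w, w1$g) -
                            merge_f_3d(pq[1], pq[2], g)))
  }
  expect_lt(maxI, 1e-9)
  expect_lt(maxf, 1e-9)
})

test_that("the three-axis double-angle transforms satisfy the coplanar identity", {
  set.seed(18)
  da <- function(v, i) { out <- 2 * v[i] * v; out[i] <- out[i] - 1; out }
  for (rep in 1:50) {
    a1 <- runif(1, 0, 2 * pi); a2 <- runif(1, 0, 2 * pi)
    u <- c(cos(a1), sin(a1), 0); v <- c(cos(a2), sin(a2), 0)
    s3 <- sum(vapply(1:3, function(i) sum(da(u, i) * da(v, i)), numeric(1)))
    u2 <- c(cos(2 * a1), sin(2 * a1)); v2 <- c(cos(2 * a2), sin(2 * a2))
    expect_equal(s3, 2 * sum(u2 * v2) + 1, tolerance = 1e-12)
  }
  ## non-unit vector with positive weight is rejected
  rv <- random_volume_5()
  rv$v[2, 2, 2, ] <- c(2, 0, 0); rv$w[2, 2, 2] <- 1
  expect_error(grey_3d(rv$v, rv$w), "non-unit")
})

test_that("3-D comparison defaults and trivial cases", {
  cfg <- pipeline_config()
  expect_equal(cfg$f_min_3d, 0.5)
  d <- c(12, 12, 12)
  w <- array(1, d)
  vx <- array(0, c(d, 3)); vx[, , , 1] <- 1
  g <- grey_3d(vx, w, sigma = 1)
  mid <- 6 + 12 * 5 + 144 * 5
  expect_equal(merge_f_3d(mid, mid + 1, g), 1, tolerance = 1e-9)
  vz <- array(0, c(d, 3)); vz[, , , 1][, 7:12, ] <- 1; vz[, , , 3][, 1:6, ] <- 1
  g2 <- grey_3d(vz, w, sigma = 1)
  p1 <- 6 + 12 * 1 + 144 * 5   # deep in the z-directed half
  p2 <- 6 + 12 * 10 + 144 * 5  # deep in the x-directed half
  expect_equal(merge_f_3d(p1, p2, g2), 0, tolerance = 1e-6)
})

test_that("adaptive smoothing picks the sigma grid minimum deterministically", {
  cfg <- pipeline_config()
  expect_equal(c(cfg$sigma_min, cfg$sigma_max, cfg$sigma_step), c(0.4, 4.0, 0.1))
  expect_equal(cfg$lambda_sigma, 1.22)
  ## perfectly uniform volume: eps = 0 for all sigma -> smallest sigma wins
  d <- c(10, 10, 10)
  w <- array(1, d)
  v <- array(0, c(d, 3)); v[, , , 1] <- 1
  as1 <- adaptive_sigma(v, w, cfg)
  expect_true(all(abs(as1$sigma - 0.4) < 1e-12))
  ## with noisy directions, a thin 2-voxel bundle keeps a smaller kernel
  ## than the interior of a wide block (where smoothing pays off)
  set.seed(3)
  d2 <- c(24, 24, 14)
  w2 <- array(0, d2); v2 <- array(0, c(d2, 3))
  noisy_dir <- function(n, sd = 45) {
    th <- rnorm(n, 0, sd) * pi / 180
    cbind(cos(th), sin(th), 0)
  }
  idx_thin <- which(array(slice.index(w2, 1) %in% 4:5 &
                            slice.index(w2, 2) %in% 4:5, d2))
  idx_wide <- which(array(slice.index(w2, 1) %in% 9:22 &
                            slice.index(w2, 2) %in% 9:22 &
                            slice.index(w2, 3) %in% 3:12, d2))
  dirs <- noisy_dir(length(idx_thin))
  for (k in 1:3) { a <- v2[, , , k]; a[idx_thin] <- dirs[, k]; v2[, , , k] <- a }
  dirs <- noisy_dir(length(idx_wide))
  for (k in 1:3) { a <- v2[, , , k]; a[idx_wide] <- dirs[, k]; v2[, , , k] <- a }
  w2[idx_thin] <- runif(length(idx_thin), 0.6, 1.4)
  w2[idx_wide] <- runif(length(idx_wide), 0.6, 1.4)
  as2 <- adaptive_sigma(v2, w2, cfg)
  expect_lt(stats::median(as2$sigma[4:5, 4:5, 4:10]),
            stats::median(as2$sigma[12:19, 12:19, 5:9]))
})

test_that("two-layer phantoms segment into the ground-truth pool count", {
  cfg <- pipeline_config()
  ph <- phantom_volume("two_layer", dims = c(20, 20, 16), bundle_width_vox = 5)
  seg <- segment_3d(list(vec = ph$vec, weight = ph$weight), cfg,
                    adaptive = FALSE, sigma = 1)
  expect_equal(max(seg$labels), 2)
  ## aligned layers merge into one pool
  ph2 <- ph
  ph2$vec[, , , 2][ph$labels == 2] <- 0
  ph2$vec[, , , 1][ph$labels == 2] <- 1
  seg2 <- segment_3d(list(vec = ph2$vec, weight = ph2$weight), cfg,
                     adaptive = FALSE, sigma = 1)
  expect_equal(max(seg2$labels), 1)
  ## crossing slabs 30 degrees apart separate
  cs <- phantom_volume("crossing_slabs", dims = c(20, 20, 16),
                       bundle_width_vox = 5, cross_angle = 30)
  seg3 <- segment_3d(list(vec = cs$vec, weight = cs$weight), cfg,
                     adaptive = FALSE, sigma = 1)
  expect_equal(max(seg3$labels), 2)
  ## watershed boundaries closed in 3-D (face adjacency)
  lab <- seg$labels
  d <- dim(lab)
  for (ax in 1:3) {
    idx <- slice.index(lab, ax)
    a <- lab[idx < d[ax]]
    sh <- switch(ax, lab[-1, , ], lab[, -1, ], lab[, , -1])
    a <- switch(ax, lab[-d[1], , ], lab[, -d[2], ], lab[, , -d[3]])
    expect_false(any(a > 0 & sh > 0 & a != sh))
  }
})
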