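test_that("edge detection parameters default to the published table", {
  cfg <- pipeline_config()
  expect_equal(cfg$count_scale, 20)
  expect_equal(cfg$canny_sigma, 3)
  expect_equal(cfg$canny_sobel_radius, 1)
  expect_equal(c(cfg$canny_hi, cfg$canny_lo), c(50, 30))
  ## translation bound sequence W / 2^i and the printed rotation bounds
  expect_equal(cfg$rigid_rot_bounds[1:6], c(180, 10, 5, 2.5, 1.25, 1))
})

test_that("edge image of an empty slide is empty, of a rectangle its boundary", {
  cfg <- pipeline_config(resolution = resolution_config(frame_w = 64, frame_h = 64))
  empty <- regional_slide(matrix(0L, 64, 64))
  E <- edge_image(empty, cfg)
  expect_true(E$empty)
  expect_equal(nrow(E$points), 0)
  cat <- matrix(0L, 64, 64); cat[10:40, 15:35] <- 1L
  rect <- regional_slide(cat, count = (cat != 0) * 6)
  Er <- edge_image(rect, cfg)
  expect_gt(nrow(Er$points), 20)
  bx <- c(10:40, 10:40, rep(10, 21), rep(40, 21)) - 1
  by <- c(rep(15, 31), rep(35, 31), 15:35, 15:35) - 1
  dmat <- sqrt(outer(Er$points[, 1], bx, "-")^2 + outer(Er$points[, 2], by, "-")^2)
  hausdorff <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  expect_lte(hausdorff, 3)
})

test_that("translation Hough matches an exhaustive accumulator oracle", {
  set.seed(8)
  E0 <- cbind(sample(0:150, 200, TRUE), sample(0:150, 200, TRUE))
  E0 <- unique(E0)
  shift <- c(12, -7)
  E1 <- sweep(E0, 2, shift, "+")
  ## registering the shifted set back onto E0 -> the inverse offset
  expect_equal(hough_translate(E1, E0, bound = 40), -shift)
  expect_equal(hough_translate(E0, E0, bound = 40), c(0, 0))
  ## exhaustive oracle: count exact coincidences for every offset
  best <- c(NA, NA); bestn <- -1
  for (tx in -15:15) for (ty in -15:15) {
    n <- sum(paste(E1[, 1] + tx, E1[, 2] + ty) %in% paste(E0[, 1], E0[, 2]))
    if (n > bestn) { bestn <- n; best <- c(tx, ty) }
  }
  expect_equal(hough_translate(E1, E0, bound = 15), best)
  expect_error(hough_translate(E1[0, , drop = FALSE], E0, 10), "no edges")
})

test_that("rotation Hough recovers a known rotation about the given centre", {
  d <- disc_edges()
  c0 <- (d$dims - 1) / 2
  E1 <- myovol:::rotate_pts(d$points, 6, c0)
  r <- hough_rotate(E1, d$points, matrix(c0, 1), bound = 10, c0 = c0, res_deg = 1,
                    dims = d$dims)
  expect_lte(abs(r$theta - (-6)), 1)
  r0 <- hough_rotate(d$points, d$points, matrix(c0, 1), bound = 10, c0 = c0,
                     res_deg = 1, dims = d$dims)
  expect_equal(r0$theta, 0)
})

test_that("pair registration recovers rigid distortions within 1 degree / 2 px", {
  d <- disc_edges()
  c0 <- (d$dims - 1) / 2
  set.seed(13)
  for (i in 1:4) {
    th <- runif(1, -15, 15); tt <- runif(2, -40, 40)
    E1 <- sweep(myovol:::rotate_pts(d$points, th, c0), 2, tt, "+")
    rr <- rigid_register_pair(E1, d$points, d$dims, pipeline_config())
    expect_lte(abs(rr$transform$theta + th), 1)
    back <- apply_rigid(rr$transform, E1)
    expect_lte(max(sqrt(rowSums((back - d$points)^2))), 2)
  }
})

test_that("a slide flipped by ~180 degrees is recovered (step-1 bound)", {
  d <- disc_edges()
  c0 <- (d$dims - 1) / 2
  E1 <- myovol:::rotate_pts(d$points, 177, c0)
  rr <- rigid_register_pair(E1, d$points, d$dims, pipeline_config())
  back <- apply_rigid(rr$transform, E1)
  expect_lte(stats::median(sqrt(rowSums((back - d$points)^2))), 1)
  expect_lte(abs((rr$transform$theta %% 360) - 183), 1)
})

test_that("stack registration passes identical slides through as identities", {
  d <- disc_edges()
  slides <- replicate(3, d$regional, simplify = FALSE)
  rr <- rigid_register_stack(slides, pipeline_config())
  for (tf in rr$transforms) {
    expect_equal(tf$theta, 0)
    expect_equal(tf$t, c(0, 0))
  }
  expect_true(all(rr$flags == "ok"))
})

test_that("empty slides are flagged and passed through", {
  d <- disc_edges()
  empty <- regional_slide(matrix(0L, d$dims[1], d$dims[2]))
  rr <- rigid_register_stack(list(d$regional, empty, d$regional), pipeline_config())
  expect_equal(rr$flags, c("ok", "empty", "ok"))
})

test_that("the coincidence objective never decreases across applied moves", {
  ## rigid_register_pair only applies score-non-decreasing moves by
  ## construction; verify the final score is at least the initial one
  d <- disc_edges()
  c0 <- (d$dims - 1) / 2
  E1 <- sweep(myovol:::rotate_pts(d$points, 9, c0), 2, c(20, -15), "+")
  s0 <- coincidence_score(E1, d$points, d$dims)
  rr <- rigid_register_pair(E1, d$points, d$dims, pipeline_config())
  expect_gte(rr$score, s0)
  ## self-registration is the identity
  rs <- rigid_register_pair(d$points, d$points, d$dims, pipeline_config())
  expect_equal(rs$transform$theta, 0)
  expect_equal(rs$transform$t, c(0, 0))
})
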