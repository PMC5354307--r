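## Synthetic slides, stacks and phantom volumes with known ground truth.
##
## The generator emulates the features the extraction and reconstruction
## stages rely on: eccentric elliptical nuclei whose major axes follow a
## prescribed direction field with angular noise, near-circular footprints
## where the field leaves the plane, low-density gaps between bundles,
## red-blood-cell-sized objects, dense placenta-like patches, and per-slide
## rigid plus smooth elastic distortion. It makes every later stage testable
## without scanned tissue.

#' Specification of a synthetic phantom slide
#'
#' @param field function `(x, y) -> c(theta, phi)` giving the local headless
#'   planar angle (deg, `[0, 180)`) and elevation (deg, `[-90, 90]`) at a
#'   region-pixel position, or a constant `c(theta, phi)`.
#' @param nuclear_density expected nuclei per 128 x 128 px region (>= 0).
#' @param angle_noise_sd per-nucleus angular noise, deg.
#' @param bundle_mask optional function `(x, y) -> logical` (TRUE = tissue);
#'   default all tissue.
#' @param rbc_density expected red-blood-cell-sized objects per region.
#' @param dense_patch_mask optional function `(x, y) -> logical` marking
#'   placenta-like high-density patches (density multiplied by
#'   `dense_factor`).
#' @param dense_factor density multiplier inside dense patches.
#' @param seed integer; fixed seed gives byte-identical output.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(field = c(0, 0), nuclear_density = 20,
                         angle_noise_sd = 5, bundle_mask = NULL,
                         rbc_density = 0, dense_patch_mask = NULL,
                         dense_factor = 4, seed = 1L) {
  stopifnot(nuclear_density >= 0, rbc_density >= 0, angle_noise_sd >= 0)
  if (!is.function(field)) {
    fv <- field
    field <- function(x, y) fv
  }
  structure(list(field = field, nuclear_density = nuclear_density,
                 angle_noise_sd = angle_noise_sd, bundle_mask = bundle_mask,
                 rbc_density = rbc_density, dense_patch_mask = dense_patch_mask,
                 dense_factor = dense_factor, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Rasterise one filled ellipse into an RGB array (in place), returning the
## modified array. Centre (cx, cy) 0-based px, full axes (a, b), angle deg.
draw_ellipse <- function(img, cx, cy, a, b, theta, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- ceiling(a / 2) + 1
  xs <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(img)
  X <- outer(rep(1, length(ys)), xs) - cx
  Y <- outer(ys, rep(1, length(xs))) - cy
  ct <- cos(theta * pi / 180); st <- sin(theta * pi / 180)
  u <- (X * ct + Y * st) / (a / 2)
  v <- (-X * st + Y * ct) / (b / 2)
  inside <- u^2 + v^2 <= 1
  if (!any(inside)) return(img)
  sub <- which(inside, arr.ind = TRUE)
  rows <- ys[sub[, 1]] + 1L; cols <- xs[sub[, 2]] + 1L
  for (ch in 1:3) img[cbind(rows, cols, ch)] <- col[ch]
  img
}

#' Render a synthetic H&E-like slide
#'
#' Nuclei are drawn as dark-purple filled ellipses (RGB approximately
#' (90, 60, 140)/255) on a pink background (approximately (240, 200, 210)/255)
#' with additive Gaussian pixel noise (sd 8/255), so the extraction stage's local colour
#' thresholds separate them robustly. Each nucleus' major axis follows the
#' local field direction plus `Normal(0, angle_noise_sd)` noise; where the
#' field elevation is large the footprint is drawn near-circular and smaller,
#' as a steeply inclined nucleus would appear in section.
#'
#' @param spec a [phantom_spec()].
#' @param tile_px rendered (square) tile edge in px (>= 64).
#' @param cfg a [resolution_config()].
#' @return list with `image` (tile_px x tile_px x 3 array in `[0, 1]`) and
#'   `truth` (data.frame of drawn nuclei: cx, cy, a, b, theta, phi, kind).
#' @export
render_slide <- function(spec, tile_px = 512L, cfg = resolution_config()) {
  stopifnot(inherits(spec, "phantom_spec"), tile_px >= 64)
  rp <- cfg$region_px
  nreg <- ceiling(tile_px / rp)
  ## feasibility: mean nucleus ~ 18 x 7 px ellipse, area ~ 99 px^2
  if (spec$nuclear_density * 110 > 0.4 * rp^2)
    stop("infeasible density: nuclei cannot be packed without heavy overlap")
  set.seed(spec$seed)
  img <- array(0, c(tile_px, tile_px, 3))
  bg <- c(240, 200, 210) / 255
  for (ch in 1:3) img[, , ch] <- bg[ch]
  truth <- list()
  for (ry in seq_len(nreg) - 1L) for (rx in seq_len(nreg) - 1L) {
    if (!is.null(spec$bundle_mask) && !spec$bundle_mask(rx, ry)) next
    dens <- spec$nuclear_density
    if (!is.null(spec$dense_patch_mask) && spec$dense_patch_mask(rx, ry))
      dens <- dens * spec$dense_factor
    n <- stats::rpois(1, dens)
    if (n > 0) {
      f <- spec$field(rx, ry)
      for (i in seq_len(n)) {
        cx <- stats::runif(1, rx * rp, min((rx + 1) * rp, tile_px) - 1)
        cy <- stats::runif(1, ry * rp, min((ry + 1) * rp, tile_px) - 1)
        th <- ang_norm180(f[1] + stats::rnorm(1, 0, spec$angle_noise_sd))
        if (abs(f[2]) > 60) { a <- 9.5; b <- 7.5 } else { a <- 18; b <- 7 }
        a <- a * stats::runif(1, 0.9, 1.1); b <- b * stats::runif(1, 0.9, 1.1)
        img <- draw_ellipse(img, cx, cy, a, b, th, c(90, 60, 140) / 255)
        truth[[length(truth) + 1L]] <-
          data.frame(cx = cx, cy = cy, a = a, b = b, theta = th, phi = f[2],
                     kind = "nucleus")
      }
    }
    nr <- stats::rpois(1, spec$rbc_density)
    for (i in seq_len(nr)) {
      cx <- stats::runif(1, rx * rp, min((rx + 1) * rp, tile_px) - 1)
      cy <- stats::runif(1, ry * rp, min((ry + 1) * rp, tile_px) - 1)
      img <- draw_ellipse(img, cx, cy, 8, 7, stats::runif(1, 0, 180),
                          c(150, 60, 90) / 255)
      truth[[length(truth) + 1L]] <-
        data.frame(cx = cx, cy = cy, a = 8, b = 7, theta = NA_real_,
                   phi = NA_real_, kind = "rbc")
    }
  }
  img <- img + array(stats::rnorm(length(img), 0, 8 / 255), dim(img))
  img[] <- pmin(1, pmax(0, img))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0), b = numeric(0),
               theta = numeric(0), phi = numeric(0), kind = character(0))
  list(image = img, truth = truth)
}

#' Synthetic ellipse table for a whole slide (no rasterisation)
#'
#' Generates the extraction-stage output (nucleus table) directly from a phantom spec
#' over an `nx x ny` region grid, for registration / assembly tests where
#' rendering full tiles would be wasteful. Areas and aspects are drawn inside
#' the smooth-muscle band so every nucleus survives the regional size filter.
#'
#' @param spec a [phantom_spec()].
#' @param nx,ny slide extent in region pixels.
#' @param cfg a [pipeline_config()].
#' @return ellipse data.frame as from [fit_ellipses()].
#' @export
synth_ellipses <- function(spec, nx, ny, cfg = pipeline_config()) {
  res <- cfg$resolution; rp <- res$region_px
  set.seed(spec$seed)
  rows <- list()
  for (ry in seq_len(ny) - 1L) for (rx in seq_len(nx) - 1L) {
    if (!is.null(spec$bundle_mask) && !spec$bundle_mask(rx, ry)) next
    dens <- spec$nuclear_density
    if (!is.null(spec$dense_patch_mask) && spec$dense_patch_mask(rx, ry))
      dens <- dens * spec$dense_factor
    n <- stats::rpois(1, dens)
    if (n == 0) next
    f <- spec$field(rx, ry)
    vertical <- abs(f[2]) > 60
    th <- ang_norm180(f[1] + stats::rnorm(n, 0, spec$angle_noise_sd))
    asp <- if (vertical) stats::runif(n, 1.1, 1.5) else stats::runif(n, 2.4, 3.4)
    area <- stats::runif(n, 150, 300)  # px^2 -> 20-41 um^2 at 0.371 um/px
    rows[[length(rows) + 1L]] <- data.frame(
      cx = stats::runif(n, rx * rp, (rx + 1) * rp - 1e-6),
      cy = stats::runif(n, ry * rp, (ry + 1) * rp - 1e-6),
      area_px = area, area_um2 = area * res$um_per_px_x * res$um_per_px_y,
      aspect = asp, theta = th, primary = TRUE, size_class = "primary")
  }
  if (!length(rows)) return(data.frame(cx = numeric(0), cy = numeric(0),
                                       area_px = numeric(0), area_um2 = numeric(0),
                                       aspect = numeric(0), theta = numeric(0),
                                       primary = logical(0), size_class = character(0)))
  do.call(rbind, rows)
}

## Smooth elastic displacement field: sum of <= 5 Gaussian bumps, rescaled so
## the analytic maximum displacement norm equals `amplitude` px.
make_bump_warp <- function(amplitude, extent_px, n_bumps = 5L, seed = 1L) {
  set.seed(seed)
  n <- sample.int(n_bumps, 1)
  cx <- stats::runif(n, 0, extent_px[1]); cy <- stats::runif(n, 0, extent_px[2])
  sd <- stats::runif(n, 0.15, 0.35) * max(extent_px)
  ax <- stats::rnorm(n); ay <- stats::rnorm(n)
  disp <- function(x, y) {
    dx <- 0; dy <- 0
    for (i in seq_len(n)) {
      g <- exp(-((x - cx[i])^2 + (y - cy[i])^2) / (2 * sd[i]^2))
      dx <- dx + ax[i] * g; dy <- dy + ay[i] * g
    }
    cbind(dx, dy)
  }
  if (amplitude > 0) {
    gx <- seq(0, extent_px[1], length.out = 120)
    gy <- seq(0, extent_px[2], length.out = 120)
    d <- disp(rep(gx, times = 120), rep(gy, each = 120))
    mx <- max(sqrt(rowSums(d^2)))
    scl <- if (mx > 0) amplitude / mx else 0
  } else scl <- 0
  list(disp = function(x, y) disp(x, y) * scl, amplitude = amplitude,
       params = list(n = n, cx = cx, cy = cy, sd = sd, ax = ax * scl, ay = ay * scl))
}

#' Distort a stack of slides with known rigid and elastic ground truth
#'
#' Applies, per slide, a rigid rotation about the frame centre plus a
#' translation (in original-image px), then a smooth elastic displacement
#' built from at most five Gaussian bumps whose maximum displacement norm
#' equals `elastic_amplitude`. Nucleus angles rotate with the rigid rotation.
#' The exact inverse ground truth is stored per slide.
#'
#' @param slides list of ellipse data.frames (one per slide).
#' @param rigid data.frame / matrix with columns `theta` (deg), `tx`, `ty`
#'   (px), one row per slide; or NULL for identity.
#' @param elastic_amplitude max elastic displacement in px (0 = none).
#' @param extent_px `c(width, height)` of the slide content in px.
#' @param seed integer seed.
#' @return list with `slides` (distorted ellipse tables) and `truth` (per
#'   slide: theta, tx, ty, centre, and the elastic warp object).
#' @export
distort_stack <- function(slides, rigid = NULL, elastic_amplitude = 0,
                          extent_px = c(2048, 2048), seed = 1L) {
  ns <- length(slides)
  if (is.null(rigid)) rigid <- data.frame(theta = numeric(ns), tx = numeric(ns),
                                          ty = numeric(ns))
  rigid <- as.data.frame(rigid)
  stopifnot(nrow(rigid) == ns)
  centre <- extent_px / 2
  out <- vector("list", ns); truth <- vector("list", ns)
  for (s in seq_len(ns)) {
    e <- slides[[s]]
    th <- rigid$theta[s] * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    warp <- make_bump_warp(elastic_amplitude, extent_px, seed = seed + 977L * s)
    if (nrow(e)) {
      p <- cbind(e$cx - centre[1], e$cy - centre[2]) %*% t(R)
      p <- sweep(p, 2, centre, "+")
      p <- sweep(p, 2, c(rigid$tx[s], rigid$ty[s]), "+")
      d <- warp$disp(p[, 1], p[, 2])
      e$cx <- p[, 1] + d[, 1]
      e$cy <- p[, 2] + d[, 2]
      e$theta <- ang_norm180(e$theta + rigid$theta[s])
    }
    out[[s]] <- e
    truth[[s]] <- list(theta = rigid$theta[s], tx = rigid$tx[s], ty = rigid$ty[s],
                       centre = centre, warp = warp)
  }
  list(slides = out, truth = truth)
}

#' Phantom direction volume with analytic ground truth
#'
#' Three geometries used throughout the 3-D tests:
#' \describe{
#'   \item{two_layer}{an x-directed slab stacked on a y-directed slab, each
#'     `bundle_width_vox` voxels thick in z; label map has two labels.}
#'   \item{cylinder}{a z-directed cylinder of diameter `bundle_width_vox`
#'     centred in the volume; analytic width is the diameter.}
#'   \item{crossing_slabs}{two in-plane slabs whose directions differ by
#'     `cross_angle` degrees, separated by one empty voxel plane in z.}
#' }
#'
#' @param geometry `"two_layer"`, `"cylinder"` or `"crossing_slabs"`.
#' @param dims `c(nx, ny, nz)` voxels, each >= 16.
#' @param bundle_width_vox bundle width in voxels (>= 2).
#' @param cross_angle crossing angle for `crossing_slabs`, deg.
#' @param pitch_um voxel pitch, um.
#' @param seed integer seed (reserved for future noisy variants).
#' @return list with `vec` (nx x ny x nz x 3 headless unit vectors),
#'   `weight`, `category`, `theta`, `labels` (ground-truth bundle labels,
#'   0 = background), and `width_um` (analytic width).
#' @export
phantom_volume <- function(geometry = c("two_layer", "cylinder", "crossing_slabs"),
                           dims = c(24, 24, 16), bundle_width_vox = 6,
                           cross_angle = 30, pitch_um = 47.488, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(all(dims >= 16))
  if (bundle_width_vox < 2) stop("unresolvable: bundle width below 2 voxels")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vec <- array(0, c(dims, 3)); weight <- array(0, dims)
  category <- array(CAT_EMPTY, dims); theta <- array(NA_real_, dims)
  labels <- array(0L, dims)
  set_vox <- function(mask, v, lab) {
    idx <- which(mask)
    for (k in 1:3) {
      vk <- vec[, , , k]; vk[idx] <- v[k]; vec[, , , k] <<- vk
    }
    weight[idx] <<- 1
    labels[idx] <<- lab
    if (abs(v[3]) > 0.87) { category[idx] <<- CAT_VERTICAL
    } else { category[idx] <<- CAT_PLANAR
             theta[idx] <<- ang_norm180(atan2(v[2], v[1]) * 180 / pi) }
  }
  co <- function(i, n) i - (n + 1) / 2  # centred coordinate
  X <- array(rep(seq_len(nx), ny * nz), dims)
  Y <- array(rep(rep(seq_len(ny), each = nx), nz), dims)
  Z <- array(rep(seq_len(nz), each = nx * ny), dims)
  w <- bundle_width_vox
  if (geometry == "two_layer") {
    z0 <- floor(nz / 2)
    set_vox(Z > z0 - w & Z <= z0, c(1, 0, 0), 1L)       # x-directed layer
    set_vox(Z > z0 & Z <= z0 + w, c(0, 1, 0), 2L)       # y-directed layer on top
    width_um <- c(w, w) * pitch_um
  } else if (geometry == "cylinder") {
    r <- w / 2
    set_vox((co(X, nx))^2 + (co(Y, ny))^2 <= r^2, c(0, 0, 1), 1L)
    width_um <- w * pitch_um
  } else {
    a <- cross_angle * pi / 180
    z0 <- floor(nz / 2)
    set_vox(Z <= min(w, z0 - 1), c(1, 0, 0), 1L)
    set_vox(Z > z0 + 1 & Z <= z0 + 1 + w, c(cos(a), sin(a), 0), 2L)
    width_um <- c(w, w) * pitch_um
  }
  list(vec = vec, weight = weight, category = category, theta = theta,
       labels = labels, width_um = width_um, pitch_um = pitch_um, dims = dims,
       geometry = geometry)
}

#' Stack of regional slides sampled from a phantom volume
#'
#' Converts phantom voxel layers into `regional_slide` objects (one per z),
#' with per-region nuclear counts and planar angles consistent with the
#' phantom's categories, for tests of assembly and 3-D inference that start
#' from regional data.
#'
#' @param vol a [phantom_volume()].
#' @param count nuclei per occupied region.
#' @return list of [regional_slide()] objects.
#' @export
phantom_to_slides <- function(vol, count = 4) {
  nz <- vol$dims[3]
  lapply(seq_len(nz), function(z) {
    regional_slide(category = vol$category[, , z],
                   theta = vol$theta[, , z],
                   count = (vol$category[, , z] != CAT_EMPTY) * count,
                   slide_number = z, um_per_pixel = vol$pitch_um)
  })
}
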