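#' Resolution and gridding configuration
#'
#' Physical scale of the scanned tiles and the two grid sizes used by the
#' extraction stages: 32 x 32 px thresholding windows (about twice a nuclear
#' width) and 128 x 128 px coarse-graining regions (about 47.5 um at the
#' high-resolution scan scale of 0.371 um/px).
#'
#' @param um_per_px_x,um_per_px_y physical pixel size of the scan, um.
#' @param region_px coarse-graining region edge, px (must be a multiple of
#'   `window_px`).
#' @param window_px local-threshold window edge, px.
#' @param frame_w,frame_h padded regional frame size, in region pixels.
#' @return a `resolution_config` list.
#' @export
resolution_config <- function(um_per_px_x = 0.371, um_per_px_y = 0.372,
                              region_px = 128L, window_px = 32L,
                              frame_w = 800L, frame_h = 1600L) {
  stopifnot(um_per_px_x > 0, um_per_px_y > 0, region_px > 0, window_px > 0,
            region_px %% window_px == 0)
  structure(list(um_per_px_x = um_per_px_x, um_per_px_y = um_per_px_y,
                 region_px = as.integer(region_px), window_px = as.integer(window_px),
                 frame_w = as.integer(frame_w), frame_h = as.integer(frame_h),
                 region_um = region_px * um_per_px_x),
            class = "resolution_config")
}

#' Full pipeline configuration
#'
#' Bundles every tunable parameter of the reconstruction with its default
#' value. Defaults are the values used for the high-resolution tissue blocks;
#' see the methods vignette for units and rationale.
#'
#' @param resolution a [resolution_config()].
#' @param seed integer seed used for every stochastic stage.
#' @param ... named overrides of any default listed below.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(resolution = resolution_config(), seed = 1L, ...) {
  cfg <- list(
    resolution = resolution,
    seed = as.integer(seed),
    ## nucleus extraction
    red_factor = 5 / 6,          # red threshold = 5/6 * window mean red
    blue_factor = 1,             # blue threshold = window mean blue
    min_area_px = 40, max_area_px = 600,
    ## regional classification
    sm_area_um2 = c(10, 60),     # smooth-muscle nucleus area range
    rbc_max_um2 = 14,            # red-blood-cell upper size (masking stage)
    aspect_planar = 2.0, aspect_vertical = 1.6,
    vertical_fraction = 5 / 9,
    iqr_max_deg = 45,
    ## rigid registration: edge detection + Hough schedule
    count_scale = 20,
    canny_sigma = 3, canny_sobel_radius = 1, canny_hi = 50, canny_lo = 30,
    rigid_steps = 7, rigid_max_iter = 10,
    rigid_rot_bounds = c(180, 10, 5, 2.5, 1.25, 1, 1),  # 6 printed + repeat
    rigid_centre_pitch = 50, rigid_centre_r1 = 200,
    ## elastic registration
    tile_px = 16L,
    a_max = 20, e_min = 0.2, b0 = 32, elastic_theta_max = 30,
    het_min_deg2 = 45^2,
    refine_radius = 1L,          # 3x3 tile neighbourhood
    substack_len = 11L,          # densest substack for the global reference
    ref_spacing = 5L,            # local-reference group size
    qc_discard_score = 0.5,
    ## stack assembly
    slice_um = 5,
    ## 3-D direction inference
    L_max = 40L,
    ## density weighting
    rM_over_l = 0.3, rm_over_l = 0.1, N0 = 10, N1 = 160,
    ## segmentation
    seg2d_var = 1.0, vert_grey_min = 10.0, f_min_2d = 0.54, planar_grey_min = 0.01,
    f_min_3d = 0.5,
    lambda_sigma = 1.22, sigma_min = 0.4, sigma_max = 4.0, sigma_step = 0.1,
    ## masks
    vessel_var = 1.0, vessel_frac_min = 0.5, vessel_min_voxels = 9,
    placenta_density_min = 4500, placenta_sigma = 4,
    placenta_lo = 0.3, placenta_hi = 0.6, placenta_min_voxels = 10000,
    ## final smoothing + widths
    smooth_radius = 1L,
    width_grid_regions = 4L, weight_min = 0.2,
    ## Statistics
    effect_interval = c(log(1) - log(1.05), log(1) - log(0.95)),
    ks_critical = 1.36, ks_subsample = 1000L, ks_reps = 1000L, ks_prob_min = 0.90
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config parameters: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}
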