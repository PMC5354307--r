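---
title: "Reconstructing 3-D smooth-muscle direction fields from serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3-D smooth-muscle direction fields from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myovol)
```

## The problem

Myometrial smooth muscle is organised in roughly cylindrical *bundles*
(200-400 µm) that merge into larger *fasciculi* (1-2 mm). No routine 3-D
imaging modality resolves this architecture: MRI-scale voxels blur it, and a
single histological section only shows it in one plane. `myovol` rebuilds a
volumetric, weighted, *headless* (a fibre direction and its negation are the
same orientation) direction field at ~50 µm voxel pitch from a stack of
serial H&E sections, exploiting the fact that a smooth-muscle cell's nucleus
is elongated along the cell's axis.

The pipeline runs in ten stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. **Nucleus extraction** (`local_threshold()`, `fit_ellipses()`) - nuclei
   stain purple against pink cytoplasm, so a pixel is nuclear when its red
   value is below 5/6 of its local 32 × 32 px window mean *and* its blue
   value is below the window mean. Connected components (8-connectivity) are
   fitted by second-moment ellipses whose area matches the component;
   components under 40 px or over 600 px are kept aside for the masking
   stages rather than treated as single nuclei.
2. **Coarse-graining** (`classify_region()`, `pad_and_grid()`) - 128 × 128 px
   regions become *region pixels*: `empty` (< 2 smooth-muscle-sized nuclei,
   10-60 µm²), `vertical` (more than 5/9 of nuclei near-circular, aspect
   < 1.6, or an unreliable direction), or `planar` with the circular median
   of the nuclear angles. Slides are padded to a fixed frame so registration
   cannot push tissue out of bounds.
3. **Rigid registration** (`rigid_register_stack()`) - Canny edges of the
   20× scaled nuclear-count image are aligned by a generalised Hough search
   alternating translation and rotation over seven steps with shrinking
   bounds (translations ±W/2^i; rotations ±180°, 10°, 5°, 2.5°, 1.25°, 1°,
   repeated for step 7), each applied move guarded to never reduce the
   1-px-tolerance edge-coincidence score.
4. **Elastic registration** (`elastic_register_slide()`,
   `order_and_register()`) - 16 × 16-region tiles are registered locally
   rigidly; a tile's search area grows until its direction field is
   heterogeneous enough to anchor a match (angle variance at least (45°)²),
   the translation search radius is the tile's mismatch energy times the
   elasticity b₀, neighbouring tiles can override each other's transforms,
   and nuclei are finally warped by an inverse-square-distance blend of the
   four nearest tile transforms. Reference slides are chosen outward from
   the least-distorted slide of the densest substack.
5. **Representative slides** (`assemble_stack()`) - slide numbers s with
   z·l_r/l_s ≤ s < (z+1)·l_r/l_s pool into one voxel-thick substacks
   (~10 sections each at 5 µm); pooled nuclei are re-classified and counts
   become per-section means, yielding a near-isotropic voxel grid.
6. **3-D direction inference** (`assign_directions()`) - each voxel's
   candidate directions are scored by how many discretised line steps stay
   inside the same inferred bundle (30° azimuth/elevation agreement,
   temporary vectors for not-yet-assigned voxels); planar voxels average
   candidate elevations (-60°..60° in 15° steps) weighted by those lengths,
   vertical voxels also search 32 azimuths at 11.25°. High-contrast voxels
   are assigned first and immediately inform later probes.
7. **Weighting** (`voxel_weights()`) - the in-plane count is corrected for
   the stereological sampling bias (an inclined nucleus is cut by more
   sections; observation probability ≈ max(r_M sin φ, r_m)/l with
   r_M/l = 0.3, r_m/l = 0.1), ramped between N₀ = 10 and N₁ = 160, and
   multiplied by the squared mean resultant of the double-angle nuclear
   direction vectors (the homogeneity weight).
8. **Segmentation** (`segment_3d()`, `segment_2d()`) - orientations are
   doubled (v' = (cos 2θ, sin 2θ) in 2-D; v⁽ⁱ⁾ = 2vᵢv − eᵢ per axis in 3-D)
   so headless directions average coherently; the anisotropy image
   I_w = Σⱼₖ gⱼgₖwⱼwₖ(c(vⱼ·vₖ)² − 1) (c = 2 or 4) has an exact closed form in
   the convolved double-angle fields, and a watershed flooded in decreasing
   anisotropy merges adjacent pools whose neighbourhood comparison
   f(p, q) ≥ f_min (0.54 in 2-D, 0.5 in 3-D), keeping boundaries closed
   without over-segmentation.
9. **Masking** (`detect_vessels()`, `detect_placenta()`) - vessels are found
   through red-blood-cell-sized objects (< 14 µm²) dominating a voxel's
   detections (26-connected clusters ≥ 9 voxels, dilated one voxel for the
   wall); placenta through all-size nuclear density ≥ 4500/mm² with σ = 4
   hysteresis smoothing (0.3/0.6) and a 10000-voxel minimum cluster.
10. **Smoothing and widths** (`final_smooth()`, `measure_widths()`,
    `equivalence_stats()`) - edges and masks are excluded from a radius-1
    Gaussian smoothing of the weighted vectors (neighbours are sign-aligned
    into the centre's hemisphere first, keeping the field headless); bundle
    widths are sampled on a random-offset lattice (4 regions ≈ 190 µm
    in-plane, 1 voxel in z) along directions perpendicular to the local
    fibre, and registered vs unregistered width distributions are compared
    by a 5% log-scale equivalence test plus a bootstrap Kolmogorov-Smirnov
    test.

## What the synthetic generator emulates - and what it does not

All tests run on phantoms from the `fixtures` functions: `render_slide()`
draws eccentric nuclear ellipses (major axis = local field direction plus
Gaussian angular noise, near-circular where the field leaves the plane) in
approximate H&E colours (nuclei RGB ≈ (90, 60, 140), background
≈ (240, 200, 210), pixel noise sd 8/255); `synth_ellipses()` produces the
same nucleus tables without rasterisation; `distort_stack()` applies known
rigid transforms plus smooth elastic warps (≤ 5 Gaussian bumps, rescaled so
the analytic maximum displacement equals the requested amplitude);
`phantom_volume()` builds two-layer, cylinder and crossing-slab volumes with
analytic labels and widths.

The phantoms capture what the algorithms consume: orientation-bearing
ellipses, bundle gaps, vertical regions, RBC-sized objects, dense
placenta-like patches, and per-slide distortion. They do **not** model
staining variability beyond local means, sectioning tears (discarded slides
are emulated by deleting slide numbers), partial-volume colour mixing, or
anisotropic scanner blur - so green tests demonstrate algorithmic
correctness under the stated geometry, not robustness to every staining
artefact of real slides.

A note on elastic-registration fixtures: the tile energy only sees structure
at the bundle scale (angle contrast above a_max = 20° and planar/empty
transitions). Fixtures therefore use an 8-region bundle patchwork with
quasi-random per-block orientations (golden-angle hashing, to avoid the
aliasing a periodic pattern would induce in the Hough accumulator) and 2-px
gaps. Smoothly varying fields without gaps are nearly invisible to the
energy - as they would be on real tissue - and are not a fair test of the
method.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `window_px` | 32 | px | local threshold window (~2 nucleus widths) |
| `region_px` | 128 | px | region pixel (47.5 µm at 0.371 µm/px) |
| `min/max_area_px` | 40 / 600 | px² | single-nucleus size band |
| `sm_area_um2` | 10-60 | µm² | smooth-muscle nucleus band |
| `aspect_planar` / `aspect_vertical` | 2.0 / 1.6 | - | planar / vertical class cut |
| `count_scale`, `canny_sigma`, `canny_hi/lo` | 20, 3, 50/30 | - | edge image + Canny |
| `a_max`, `e_min`, `b0` | 20°, 0.2, 32 (16 for the smaller blocks) | - | elastic match tolerance, energy gate, elasticity |
| `L_max` | 40 | voxels | probe cap (unstated in the source method; 40 ≈ 2 mm keeps probes local at ~50 µm pitch) |
| `rM_over_l`, `rm_over_l`, `N0`, `N1` | 0.3, 0.1, 10, 160 | - | stereological correction and density ramp |
| `f_min_2d` / `f_min_3d` | 0.54 / 0.5 | - | watershed merge thresholds (both as published) |
| `lambda_sigma`, sigma grid | 1.22, 0.4-4.0 step 0.1 | voxels | adaptive smoothing trade-off |
| `weight_min` | 0.2 | - | tissue threshold for 3-D width sampling |

## Numerical choices and degenerate inputs

* **Circular statistics.** Planar angles are headless; the circular median
  minimises the summed headless distance with ties to the smaller angle, the
  circular IQR is taken after rotating the median to 90°, and the
  heterogeneity "variance" is the Fréchet variance (minimum over mean
  directions of the mean squared headless deviation) - for a 50/50 mixture
  90° apart this is exactly (45°)², the tile-expansion threshold. The
  regional direction uses the median over *all* size-filtered nuclei in the
  region, matching the published rule.
* **Convolutions** are separable Gaussians truncated at 3σ, renormalised to
  sum 1, with zero padding (no tissue outside the frame). The watershed's
  closed forms are pinned to the brute-force double sums at 1e-9 in the
  tests; the weighted 3-D anisotropy subtracts (G\*W)², the only reading
  consistent with the unweighted identity.
* **Hough accumulators** use 1 px translation bins; rotation candidates are
  1° wide while the bound exceeds 5° and bound/5 (minimum 0.25°) below that,
  since sub-degree bounds imply sub-degree rotations. Moves are only applied
  if the 1-px-tolerance coincidence score does not decrease, which makes the
  rigid objective monotone by construction. Exact-bin hits break ties so
  sub-tolerance alignments win.
* **Degenerate inputs.** Empty slides pass through rigid registration
  flagged; tiles with no planar pixels or no admissible transform keep the
  identity; a voxel with no qualifying probe lengths takes elevation 0
  (planar) or the vertical default (θ = 0, φ = 90, flagged low-confidence);
  zero weight at a watershed point forces f = 0 (nothing merges through
  empty tissue); `density_weight()` at dz = 0 falls back to the minor-axis
  floor rather than dividing by zero.
* **Adaptive smoothing.** The scale is chosen per voxel as the grid argmin
  of λσ² + ε², where ε² compares the *smoothed* field at the voxel's
  first-order neighbourhood (and itself) with the voxel's *raw* field. In
  noisy homogeneous tissue the smoothed neighbourhood approaches the local
  mean and ε falls with σ, so wide bundles earn large kernels; across a thin
  bundle smoothing drags in empty surroundings and ε rises, keeping kernels
  small. On a perfectly uniform volume ε vanishes for every σ and the
  λσ² term with the smaller-σ tie rule selects the grid minimum.
* **Width tracing** steps 0.5 voxel along ± the width direction until the
  containing cell fails the tissue test; the reported width is the distance
  between the two stop points minus one step, which is unbiased against the
  continuous segment length and exact for axis-aligned slabs.
* **Determinism.** Every stochastic step (phantom generation, grid offsets,
  perpendicular direction draws, bootstrap subsampling) consumes an explicit
  seed; identical configuration and seed reproduce artifacts byte for byte,
  which the stage cache exploits.

## Design choices where the method left room

* Windows at image borders keep their own mean; coordinates are 0-based with
  y down, angles counter-clockwise in that frame.
* The rotation-bound sequence lists six entries for seven steps; the final
  ±1° is repeated.
* The elastic neighbourhood for transform refinement is the 3 × 3 tile
  block - the smallest symmetric choice - updated simultaneously from the
  original assignments; the densest-substack length for global-reference
  selection is 11 slides; slides whose post-registration match score exceeds
  0.5 are flagged for discarding, replacing the published manual visual
  inspection (QC overlays are still written).
* The 5/9 vertical-fraction rule counts indeterminate nuclei (aspect
  1.6-2.0) in both class tallies, with the doubled tally in the denominator.
* Equidistant nearest-slide ties in the substack extension resolve to the
  lower slide number; watershed ties in anisotropy resolve by raster index;
  a pool's "local maximum" is its first (highest) point.
* The distribution-equivalence verdict requires the bootstrap
  P(√(nm/(n+m))·D < 1.36) to reach 0.90, the operational rule consistent
  with the published per-block probabilities (one block sits at 0.9486 and
  is still declared equivalent).
* Direction volumes are written as NIfTI (vector field plus weight
  companion); regional slides as 3-plane 16-bit TIFF with a JSON sidecar.

## Problem sizes used by the tests

The suite exercises every stage at reduced, fixed sizes chosen to keep the
study conditions honest while staying comfortably reproducible: 96-256 px
rendered tiles, 48-192-region slide frames, 8-12-slide stacks, phantom
volumes of 16³-40·30² voxels, 20 rigid pairs, 3 elastic warp seeds, 2000
width samples against an 8000-draw chord oracle, and 20-seed equivalence
panels with 400 bootstrap repetitions (the statistics themselves default to
1000 repetitions and 1000-value subsamples). Equivalence panels draw 50000
value parent samples so the parent-to-subsample ratio matches the regime of
the real width data sets.

## Known limitations

* Adjacent parallel bundles merge: without a collagen counterstain the
  anisotropy image cannot separate structures whose directions agree.
* Vessels not filled with red blood cells at fixation are missed, as are
  placenta-like regions below the density threshold.
* The elastic model is locally rigid with blended transforms - it corrects
  smooth distortion up to b₀, not folds or tears (such sections should be
  discarded upstream, encoded as gaps in the slide numbering).
* The final volume inherits whatever distortion the global reference slide
  carries; the reference is chosen to minimise, not eliminate, it.
* Width measurements below ~2 voxels (≈ 100 µm) are unresolvable at the
  working pitch.

## A minimal end-to-end run

```{r, eval = FALSE}
cfg <- pipeline_config(resolution = resolution_config(frame_w = 64, frame_h = 64),
                       b0 = 8, substack_len = 5, ref_spacing = 3, N0 = 4)
rp <- cfg$resolution$region_px
field <- function(x, y) c((137.508 * (floor(x / 8) * 13 + floor(y / 8) * 7)) %% 180, 0)
gaps <- function(x, y) (x %% 8 > 1) & (y %% 8 > 1)
spec <- phantom_spec(field = field, nuclear_density = 8, angle_noise_sd = 4,
                     bundle_mask = gaps, seed = 100)
e <- synth_ellipses(spec, 48, 48, cfg)
nums <- c(1, 2, 4, 5, 8, 10, 13, 14)
slides <- setNames(lapply(seq_along(nums), function(k)
  distort_stack(list(e),
                rigid = data.frame(theta = runif(1, -5, 5),
                                   tx = runif(1, -3, 3) * rp,
                                   ty = runif(1, -3, 3) * rp),
                elastic_amplitude = 2 * rp, extent_px = c(48, 48) * rp,
                seed = 200 + k)$slides[[1]]), nums)
out <- run_pipeline(slides, cfg, out_dir = tempfile("myovol"), total_slides = 28)
out$summary
width_maps(out$widths$samples)$z_profile
```
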