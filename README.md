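# myovol

Three-dimensional reconstruction of smooth-muscle direction fields from
serial histological sections.

## What it is for

The myometrium - the muscular wall of the uterus - is built from roughly
cylindrical bundles (200-400 µm) of similarly oriented myocytes that merge
into larger fasciculi. This architecture shapes how excitation spreads, but
no routine 3-D modality resolves it. `myovol` rebuilds it from serial
H&E-stained sections for anyone studying visceral smooth-muscle
microarchitecture (uterus, gut, vasculature): it extracts nuclear
orientations from the scanned slides, registers the sections rigidly and
elastically, and infers a weighted, headless unit-vector field **v**(p) on a
~50 µm voxel grid, together with a fascicle segmentation, tissue masks, and
bundle-width morphometry.

The core quantities, in the field's usual notation:

* Regional orientation: per 128×128 px region, the circular median of the
  nuclear major-axis angles θ ∈ [0°, 180°) (planar), or a *vertical* /
  *empty* class.
* Registration: generalised Hough transforms T(S) = M_θ S + t, whole-slide
  first, then locally rigid per 16×16-region tile with elasticity
  b(A) = b₀·e(A, T₀), where e is the fraction of unmatched region pixels.
* 3-D inference: v = (cos θ cos φ, sin θ cos φ, sin φ) chosen to maximise
  the distance L(p, v) to the inferred bundle boundary along the probe line.
* Weights: w = w_d · w_h with the stereological inversion
  N = min(N_p l/(r_M d_z), N_p l/r_m) ramped on [N₀, N₁], and
  w_h = |Σ v(θᵢ, φ)|²/|S|² over the double-angle nuclear vectors.
* Segmentation: watershed-with-merging on the double-angle anisotropy
  I_w(p) = Σ_{jk} g_j g_k w_j w_k (c (v_j·v_k)² − 1), merging pools whose
  comparison f(p, q) reaches f_min.
* Verification: registered vs unregistered bundle-width distributions must
  agree within a 5% effect (log-mean CI inside (−0.0488, 0.0513)) and pass a
  bootstrap Kolmogorov-Smirnov test at the 1.36 critical value.

## Worked example

Reconstruct a 12-slide synthetic stack with known ground truth (the same
generator the tests use):

```r
library(myovol)
cfg <- pipeline_config(resolution = resolution_config(frame_w = 64, frame_h = 64),
                       b0 = 8, substack_len = 5, ref_spacing = 3, N0 = 4)
rp <- cfg$resolution$region_px
field <- function(x, y) c((137.508 * (floor(x / 8) * 13 + floor(y / 8) * 7)) %% 180, 0)
gaps <- function(x, y) (x %% 8 > 1) & (y %% 8 > 1)
spec <- phantom_spec(field = field, nuclear_density = 8, angle_noise_sd = 4,
                     bundle_mask = gaps, seed = 100)
e <- synth_ellipses(spec, 48, 48, cfg)
nums <- c(1, 2, 4, 5, 8, 10, 13, 14, 18, 21, 25, 28)  # gaps = discarded sections
set.seed(42)
slides <- setNames(lapply(seq_along(nums), function(k)
  distort_stack(list(e),
                rigid = data.frame(theta = runif(1, -5, 5),
                                   tx = runif(1, -3, 3) * rp,
                                   ty = runif(1, -3, 3) * rp),
                elastic_amplitude = 2 * rp, extent_px = c(48, 48) * rp,
                seed = 200 + k)$slides[[1]]), nums)
out <- run_pipeline(slides, cfg, total_slides = 28)
str(out$summary)
#> List of 5
#>  $ total_slides              : num 28
#>  $ slides_before_registration: int 12
#>  $ slides_after_rigid        : int 12
#>  $ slides_after_registration : int 12
#>  $ proportion_used           : num 43
median(out$widths$samples$width_um)
#> [1] 166.2079
```

The summary is the bookkeeping table of the run: 12 of the 28 numbered
sections survived to the final volume (43%). The stack condenses into
representative slides one voxel thick, every non-empty voxel carries a unit
direction and a weight in [0, 1], and the width report samples bundle
widths (here a median of ~166 µm for 6-region-wide synthetic bundles at
47.5 µm pitch, measured perpendicular to the local direction, which crosses
the bundles obliquely as often as squarely). A thin command-line wrapper
with one subcommand per stage lives at `inst/cli/myovol.R`.

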