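# patchtv

Combined nonlocal-patch and total-variation (patch-TV) image reconstruction
for limited-view two-dimensional photoacoustic tomography (PAT), with a
straight-line detector scanning geometry.

## The problem

Photoacoustic tomography fires a short laser pulse into tissue; absorbed
optical energy launches an ultrasound wave that is recorded by transducers
outside the object. In 2D, under the standard assumptions, the time-integrated
pressure at a detector equals the integral of the absorbed-energy image over a
circle centred at the detector with radius `c·t` — so reconstruction means
inverting a circular-mean (arc-integral) transform.

This package targets the deliberately hard *limited-view* configuration in
which all detectors lie on one straight line beside the object (76 mm line,
38 mm from the image centre, 10–50 sampling points). A large angular range of
projections is never measured, the discrete forward operator has a large null
space, and naive inversion produces severe streaks. The patch-TV solver
regularises the inversion with two complementary priors:

```
minimise  ||M A - g||²  +  α · TV(A)  +  β · ||(I - H) A||²
```

* `M` — sparse arc-quadrature projection matrix (built in compiled code),
* `TV` — isotropic total variation (edge-preserving local prior),
* `H` — a row-stochastic *nonlocal* operator whose rows average pixels with
  similar surroundings anywhere in the image, using steering-kernel
  (structure-tensor adaptive) weights combined with Gaussian-windowed patch
  dissimilarity. `H` is rebuilt from the current iterate each iteration.

The objective is minimised by variable splitting: an exact closed-form
shrinkage step for the gradient field, an exact FFT solve for the image
update, a Bregman-style feedback variable, and Barzilai–Borwein step sizes.
Baselines for comparison: gradient-descent TV (`tv_gd_reconstruct()`),
patch-only regularisation (`patch_re_reconstruct()`), and scaled
backprojection (`backproject()`).

## Worked example

A small end-to-end run (32 × 32 Shepp–Logan, 12 detectors, honest
supersampled data — the package refuses to simulate with the reconstruction
operator):

```r
library(patchtv)

spec <- make_shepp_logan()                      # analytic 10-ellipse phantom
grid <- rasterize(spec, 32, 32)                 # reference image
det  <- detector_line(12, orientation = "vertical")
tg   <- ensure_time_coverage(time_grid(fs_hz = 1e7), det, spec$extent)
g    <- simulate_signals(spec, det, tg, supersample = 2L)   # fine-grid data
proj <- build_projection_matrix(grid, det, tg)              # coarse-grid M

rec <- patch_tv_reconstruct(
  g, proj,
  solver_params(alpha = 0.4, beta = 0.35, max_iters = 10L),
  patch_config(), reference = grid)

glance(rec)
#> # A tibble: 1 × 6
#>   solver   iters_run converged final_objective final_d runtime_s
#>   <chr>        <int> <lgl>               <dbl>   <dbl>     <dbl>
#> 1 patch_tv        10 FALSE                37.3   0.384     0.959

tidy(rec)          # per-iteration objective and relative distance d
#> # A tibble: 10 × 4
#>    solver   iteration objective     d
#>  1 patch_tv         1      38.5 0.571
#>  2 patch_tv         2      34.4 0.534
#>  ⋮
#> 10 patch_tv        10      37.3 0.384

autoplot(rec)      # reconstructed image, ggplot2
```

Or drive a whole comparison from a bundled YAML config:

```r
cfg <- system.file("extdata", "configs", "smoke_32.yaml", package = "patchtv")
exp <- run_experiment(experiment_config(cfg))
exp$metrics
#> # A tibble: 4 × 8
#>   experiment solver         n_points snr_db psnr_db d_final iters runtime_s
#> 1 smoke_32   patch_tv             12    Inf    16.1   0.388    10    0.955
#> 2 smoke_32   patch_re             12    Inf    16.2   0.386    10    1.10
#> 3 smoke_32   tv_gd                12    Inf    13.2   0.545    10    0.0890
#> 4 smoke_32   backprojection       12    Inf    12.8   0.567     1    0.0560

plot_convergence(exp)
```

The same runner is scriptable from the shell:

```sh
Rscript inst/cli/patv.R run inst/extdata/configs/smoke_32.yaml --out /tmp/run
Rscript inst/cli/patv.R plot /tmp/run
```

which writes `metrics.csv`, `iterations.csv`, per-solver image TSV/PNGs, a
`run.log` with the config hash, and a convergence figure.

## The full simulation study

Four bundled configurations regenerate the full study (128 × 128 raster,
76.8 mm field, 10 iterations, perpendicular and horizontal scanning lines,
noiseless and noisy data). Measured PSNR (dB) of the final iterate:

| experiment | points | patch_tv | patch_re | tv_gd |
|---|---|---|---|---|
| Shepp–Logan, perpendicular | 50 / 20 / 10 | 16.60 / 16.65 / 16.66 | 16.42 / 16.43 / 16.26 | 13.43 / 13.46 / 13.49 |
| Shepp–Logan, horizontal | 50 / 20 / 10 | 14.60 / 14.73 / 14.89 | 14.14 / 14.26 / 14.37 | 11.88 / 11.92 / 11.99 |
| FORBILD-style, perpendicular | 50 / 20 / 10 | 15.34 / 15.38 / 15.38 | 15.41 / 15.46 / 15.29 | 12.01 / 12.04 / 12.06 |
| FORBILD-style, 20 pts, SNR 10/5/0 dB | 20 | 15.19 / 15.12 / 13.70 | — | 11.79 / 11.81 / 11.82 |

Patch-TV beats plain TV by 1.9–3.2 dB everywhere, degrades gracefully with
noise, and attains the smallest final relative distance `d` in the sparsest
FORBILD case (0.351 vs 0.355 patch-only and 0.515 TV). Two caveats the test
suite reports honestly: published PSNR figures for this geometry are far
higher than any solver of this model class can reach with non-inverse-crime
data (unregularised least squares semi-converges near 19 dB and even fully
converged TV stays near 20 dB, so the absolute published values are not
reproduced — see the methods vignette's Limitations section), and in this
under-determined 10-iteration regime quality is nearly flat in the detector
count rather than strictly decreasing.

## Reproduction

Everything is deterministic given a config (noise seeds are derived from the
config seed). To reproduce from a clean checkout:

```sh
R CMD INSTALL --no-docs --no-html --no-help .

# full test suite (unit + property + acceptance) against the installed package
Rscript -e 'testthat::test_dir("tests/testthat", package = "patchtv",
                               load_package = "installed")'

# headline acceptance quantities as JSON
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The acceptance script reruns the Shepp–Logan perpendicular study and the
FORBILD 10-point comparison and writes final PSNR/d per solver and sampling
density. The test suite's tier-2 acceptance blocks compare the regenerated
tables against published values at ±3 dB; as explained above, those
particular blocks fail by design of honesty (the measured reconstruction
ceiling is documented in the vignette), while all numerical-primitive gates
and the qualitative solver-ordering and noise-robustness claims pass.

## Package layout

* `R/phantoms.R`, `R/grid.R` — analytic ellipse phantoms (Shepp–Logan,
  FORBILD-style), block-averaged rasterisation, the `pa_grid` image class.
* `R/forward.R`, `src/projector.cpp` — detector/time geometry, sparse arc
  projector, supersampled simulation, noise injection, signal CSV I/O.
* `R/nonlocal.R`, `src/nonlocal.cpp` — structure tensors, steering kernels,
  the sparse nonlocal operator `H`.
* `R/solver-ops.R`, `R/reconstruct.R` — shrinkage / FFT image update / BB
  primitives and the four reconstruction drivers.
* `R/metrics.R`, `R/tidiers.R` — PSNR, relative distance `d`, TV value,
  `tidy()` / `glance()` / `autoplot()` methods.
* `R/experiments.R`, `inst/cli/patv.R` — YAML-configured experiment runner
  and command-line interface.
* `vignettes/patchtv-methods.Rmd` — model, discretisation, solver and
  regulariser details, and known limitations.
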