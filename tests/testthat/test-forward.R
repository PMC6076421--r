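test_that("detector lines are placed and spaced correctly", {
  d <- detector_line(5, line_length_mm = 76, distance_mm = 38, "vertical")
  expect_equal(d$positions[, "x"], rep(38, 5))
  expect_equal(d$positions[, "y"], seq(-38, 38, length.out = 5))
  h <- detector_line(3, orientation = "horizontal")
  expect_equal(h$positions[, "y"], rep(38, 3))
  expect_equal(unname(h$positions[1, "x"]), -38)
  one <- detector_line(1)
  expect_equal(unname(one$positions[1, ]), c(38, 0))
  expect_error(detector_line(0))
})

test_that("time grids count samples and bins correctly", {
  tg <- time_grid(fs_hz = 200e6, duration_s = 20e-6)
  expect_equal(tg$n_samples, 4000)
  expect_equal(patchtv:::default_downsample(tg, 1024L), 4L)
  bins <- patchtv:::time_bin_centers(tg, 4L)
  expect_length(bins, 1000)
  expect_equal(bins[1], 0.5 * 4 / 200e6)  # first bin centre
  ts <- patchtv:::time_samples(tg)
  expect_equal(ts[1], 0)
  expect_equal(diff(ts)[1], 1 / 200e6)
})

test_that("ensure_time_coverage extends too-short windows with a warning", {
  det <- detector_line(10)
  tg <- time_grid()                     # 20 us: spans only 30 mm
  expect_warning(tg2 <- ensure_time_coverage(tg, det, 76.8), "extending")
  rr <- patchtv:::detector_radial_range(det, 76.8)
  c_mm_s <- tg2$c * 1e3
  expect_lte(tg2$t_offset, rr[["rmin"]] / c_mm_s)
  expect_gte(tg2$t_offset + tg2$duration, rr[["rmax"]] / c_mm_s)
  # an already-covering window is returned unchanged
  big <- time_grid(duration_s = 1e-4)
  expect_identical(ensure_time_coverage(big, det, 76.8), big)
})

test_that("forward operator satisfies the adjoint identity", {
  fx <- fx_small()
  M <- fx$proj$M
  set.seed(11)
  x <- rnorm(ncol(M))
  y <- rnorm(nrow(M))
  lhs <- sum(as.vector(M %*% x) * y)
  rhs <- sum(x * as.vector(Matrix::crossprod(M, y)))
  expect_equal(lhs, rhs, tolerance = 1e-13)
})

test_that("projector rows are non-negative and ordered detector-major", {
  fx <- fx_small()
  expect_true(all(fx$proj$M@x >= 0))
  img <- matrix(runif(32 * 32), 32, 32)
  sig <- forward_apply(fx$proj, img)
  expect_equal(patchtv:::signals_vec(sig),
               as.vector(fx$proj$M %*% as.vector(img)))
})

test_that("uniform image signals match the analytic arc-clipping oracle", {
  spec <- make_shepp_logan()
  det <- detector_line(5)
  tg <- suppressWarnings(
    ensure_time_coverage(time_grid(fs_hz = 10e6), det, spec$extent))
  grid <- rasterize(spec, 96, 96)
  proj <- build_projection_matrix(grid, det, tg, samples_per_pixel = 8)
  v <- 1.7
  got <- forward_apply(proj, matrix(v, 96, 96))
  hw <- 76.8 / 2
  arc_len <- function(x0, y0, r, nang = 2e5) {
    th <- (seq_len(nang) - 0.5) / nang * 2 * pi
    x <- x0 + r * cos(th)
    y <- y0 + r * sin(th)
    mean(abs(x) <= hw & abs(y) <= hw) * 2 * pi * r
  }
  checked <- 0L
  for (l in c(1L, 3L)) {
    for (k in seq(1L, length(proj$times), by = 37L)) {
      r <- tg$c * 1e3 * proj$times[k]
      al <- arc_len(det$positions[l, 1], det$positions[l, 2], r)
      if (al > 5) {
        expect_lt(abs(got$values[l, k] - v * al) / (v * al), 0.01)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 20L)
})

test_that("forward model is linear", {
  fx <- fx_small()
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  ga <- forward_apply(fx$proj, a)$values
  gb <- forward_apply(fx$proj, b)$values
  gab <- forward_apply(fx$proj, 2 * a + 3 * b)$values
  expect_equal(gab, 2 * ga + 3 * gb, tolerance = 1e-12)
})

test_that("simulate_signals refuses the inverse crime", {
  fx <- fx_small()
  expect_error(simulate_signals(fx$spec, fx$det, fx$tg, supersample = 1L),
               "inverse crime")
})

test_that("g_from_pressure integrates constant pressure analytically", {
  det <- detector_line(2)
  tg <- time_grid(fs_hz = 1e6, duration_s = 1e-5)
  p0 <- 3.5
  p <- matrix(p0, 2, tg$n_samples)
  g <- g_from_pressure(p, tg, det, Cp = 4000, beta_exp = 4e-4)
  tt <- patchtv:::time_samples(tg)
  expected <- 4 * pi * 4000 / 4e-4 * tt^2 * p0
  expect_equal(g$values[1, ], expected, tolerance = 1e-12)
  expect_equal(g$values[2, ], expected, tolerance = 1e-12)
})

test_that("add_noise hits the target SNR and is reproducible", {
  det <- detector_line(4)
  times <- seq(1e-6, 4e-4, length.out = 5000)
  sig <- pa_signals(matrix(sin(seq_len(4 * 5000)), 4, 5000), det, times)
  noisy <- add_noise(sig, 20, seed = 99)
  emp_snr <- 10 * log10(mean(sig$values^2) /
                          mean((noisy$values - sig$values)^2))
  expect_lt(abs(emp_snr - 20), 0.1)
  # determinism and RNG-state restoration
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  n1 <- add_noise(sig, 5, seed = 7)
  n2 <- add_noise(sig, 5, seed = 7)
  after <- rnorm(1)
  expect_identical(n1$values, n2$values)
  expect_identical(before, after)
  # infinite SNR is a no-op; zero signal is rejected
  expect_identical(add_noise(sig, Inf)$values, sig$values)
  zero <- pa_signals(matrix(0, 4, 5000), det, times)
  expect_error(add_noise(zero, 10), "all-zero")
})

test_that("signal CSV round trip preserves values and times", {
  fx <- fx_small()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_signals_csv(fx$g, path)
  back <- read_signals_csv(path, fx$det)
  expect_equal(back$values, fx$g$values, tolerance = 1e-10)
  expect_equal(back$times, fx$g$times, tolerance = 1e-10)
})

test_that("projection matrix validates the geometry", {
  grid <- pa_grid(matrix(0, 16, 16), extent = 76.8)
  det <- detector_line(4, distance_mm = 60)   # line outside the image
  # a window far too early records no arc touching the image
  tg <- time_grid(fs_hz = 200e6, duration_s = 1e-7)
  expect_error(build_projection_matrix(grid, det, tg), "no recorded arc")
})
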