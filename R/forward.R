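#' Straight-line detector geometry
#'
#' Detectors are uniformly spaced (endpoints included) along a straight line
#' at `distance_mm` from the image centre: `orientation = "vertical"` puts
#' the line parallel to the y axis at `x = +distance_mm` (the default study
#' scan on the right of the phantom), `"horizontal"` parallel to the x axis
#' at `y = +distance_mm`.
#'
#' @param n_points number of sampling points on the line.
#' @param line_length_mm line length in mm.
#' @param distance_mm distance from the image centre to the line, mm.
#' @param orientation `"vertical"` (parallel to y) or `"horizontal"`.
#' @return A `pa_detectors` object with a `positions` matrix (x, y in mm).
#' @export
detector_line <- function(n_points, line_length_mm = 76,
                          distance_mm = 38,
                          orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  stopifnot(n_points >= 1, line_length_mm > 0)
  s <- if (n_points == 1L) 0 else
    seq(-line_length_mm / 2, line_length_mm / 2, length.out = n_points)
  pos <- if (orientation == "vertical")
    cbind(x = rep(distance_mm, n_points), y = s)
  else
    cbind(x = s, y = rep(distance_mm, n_points))
  structure(list(n_points = n_points, line_length = line_length_mm,
                 distance = distance_mm, orientation = orientation,
                 positions = pos),
            class = "pa_detectors")
}

#' @exportS3Method
print.pa_detectors <- function(x, ...) {
  cat(sprintf("<pa_detectors> %d points, %s line, length %g mm, %g mm from centre\n",
              x$n_points, x$orientation, x$line_length, x$distance))
  invisible(x)
}

#' Time sampling of the recorded signals
#'
#' @param fs_hz sampling frequency in Hz.
#' @param duration_s recording duration in s.
#' @param t_offset_s start of the recording window in s.
#' @param c_mps speed of sound in m/s (1500 by default, soft tissue).
#' @return A `pa_timegrid` with `n_samples = round(fs_hz * duration_s)`.
#' @export
time_grid <- function(fs_hz = 200e6, duration_s = 20e-6, t_offset_s = 0,
                      c_mps = 1500) {
  stopifnot(fs_hz > 0, duration_s > 0, c_mps > 0, t_offset_s >= 0)
  structure(list(fs = fs_hz, duration = duration_s, t_offset = t_offset_s,
                 c = c_mps, n_samples = round(fs_hz * duration_s)),
            class = "pa_timegrid")
}

#' @exportS3Method
print.pa_timegrid <- function(x, ...) {
  cat(sprintf("<pa_timegrid> fs %.4g MHz, window [%.3g, %.3g] us, c %g m/s (%d samples)\n",
              x$fs / 1e6, x$t_offset * 1e6, (x$t_offset + x$duration) * 1e6,
              x$c, x$n_samples))
  invisible(x)
}

# raw sample times (s), full rate
time_samples <- function(tg) tg$t_offset + (seq_len(tg$n_samples) - 1) / tg$fs

# centres of the downsampled solver bins
time_bin_centers <- function(tg, downsample) {
  nb <- floor(tg$n_samples / downsample)
  tg$t_offset + (seq_len(nb) - 0.5) * downsample / tg$fs
}

default_downsample <- function(tg, max_bins = 1024L) {
  max(1L, ceiling(tg$n_samples / max_bins))
}

# radial reach of a detector set over a centred square of width `extent`:
# smallest and largest |r - r0| over the square, across all detectors
detector_radial_range <- function(det, extent) {
  hw <- extent / 2
  px <- det$positions[, 1]; py <- det$positions[, 2]
  dx <- pmax(abs(px) - hw, 0); dy <- pmax(abs(py) - hw, 0)
  rmin <- min(sqrt(dx^2 + dy^2))
  cx <- outer(px, c(-hw, hw), "-"); cy <- outer(py, c(-hw, hw), "-")
  rmax <- 0
  for (sx in 1:2) for (sy in 1:2)
    rmax <- max(rmax, sqrt(cx[, sx]^2 + cy[, sy]^2))
  c(rmin = rmin, rmax = rmax)
}

#' Extend a time grid to cover the imaging region
#'
#' With the default speed of sound a 20 microsecond window spans only 30 mm
#' of radius, which cannot cover a 76.8 mm image scanned from 38 mm away;
#' this helper widens (never shrinks) the window so every image point is
#' reachable, warning when it overrides the configured window.
#'
#' @param tg a [time_grid()].
#' @param det a [detector_line()].
#' @param extent image width in mm.
#' @return A `pa_timegrid` covering radii from the nearest to the farthest
#'   image point.
#' @export
ensure_time_coverage <- function(tg, det, extent) {
  rr <- detector_radial_range(det, extent)
  c_mm_s <- tg$c * 1e3                       # mm per second
  t0 <- rr[["rmin"]] / c_mm_s
  t1 <- rr[["rmax"]] / c_mm_s
  if (tg$t_offset <= t0 && tg$t_offset + tg$duration >= t1) return(tg)
  new_t0 <- min(tg$t_offset, t0)
  new_t1 <- max(tg$t_offset + tg$duration, t1)
  warning(sprintf(
    "time window [%.3g, %.3g] us does not cover the image (needs [%.3g, %.3g] us); extending",
    tg$t_offset * 1e6, (tg$t_offset + tg$duration) * 1e6,
    t0 * 1e6, t1 * 1e6), call. = FALSE)
  time_grid(fs_hz = tg$fs, duration_s = new_t1 - new_t0,
            t_offset_s = new_t0, c_mps = tg$c)
}

#' Build the discrete forward projector
#'
#' Discretizes the circular-mean forward model: sample `(l, k)` of the
#' integrated signal is the arc integral of the image over the circle of
#' radius `c * t_k` centred on detector `l`, clipped to the image support.
#' Each row holds non-negative arc-quadrature weights (mm) deposited onto
#' pixel centres by bilinear interpolation of equally spaced arc samples.
#' Rows are ordered detector-major with time bins fastest, matching
#' column-major vectorisation of the signal matrix.
#'
#' @param grid a [pa_grid()] defining the reconstruction raster (its values
#'   are ignored; only the geometry is used).
#' @param det a [detector_line()].
#' @param tg a [time_grid()]; the window must reach the image (see
#'   [ensure_time_coverage()]).
#' @param downsample keep every `downsample`-th raw time sample as one solver
#'   bin; default picks the smallest factor giving at most `max_bins` bins.
#' @param max_bins bin budget per detector used by the default `downsample`.
#' @param samples_per_pixel arc-quadrature density (samples per crossed
#'   pixel length; at least 4 in the default).
#' @return A `pa_projection` holding the sparse operator `M` of dimension
#'   `(n_detectors * n_bins) x (nx * ny)`.
#' @export
build_projection_matrix <- function(grid, det, tg, downsample = NULL,
                                    max_bins = 1024L,
                                    samples_per_pixel = 4) {
  stopifnot(inherits(grid, "pa_grid"), inherits(det, "pa_detectors"),
            inherits(tg, "pa_timegrid"))
  if (is.null(downsample)) downsample <- default_downsample(tg, max_bins)
  times <- time_bin_centers(tg, downsample)
  radii <- tg$c * 1e3 * times                 # mm
  ext <- grid_extent(grid)
  rr <- detector_radial_range(det, max(ext))
  if (max(radii) < rr[["rmin"]] || min(radii) > rr[["rmax"]])
    stop("no recorded arc intersects the image; check the time window and geometry")
  nb <- length(times)
  x0 <- grid_x_centers(grid)[1]
  y0 <- grid_y_centers(grid)[1]
  ii <- vector("list", det$n_points)
  jj <- vector("list", det$n_points)
  xx <- vector("list", det$n_points)
  for (l in seq_len(det$n_points)) {
    tr <- arc_row_triplets(grid$nx, grid$ny, grid$pixel_size, x0, y0,
                           det$positions[l, 1], det$positions[l, 2],
                           radii, samples_per_pixel)
    ii[[l]] <- tr$i + (l - 1L) * nb
    jj[[l]] <- tr$j
    xx[[l]] <- tr$x
  }
  M <- Matrix::sparseMatrix(i = unlist(ii) + 1L, j = unlist(jj) + 1L,
                            x = unlist(xx),
                            dims = c(det$n_points * nb, grid$nx * grid$ny))
  structure(list(M = M, det = det, tg = tg, times = times,
                 downsample = downsample, nx = grid$nx, ny = grid$ny,
                 pixel_size = grid$pixel_size),
            class = "pa_projection")
}

#' @exportS3Method
print.pa_projection <- function(x, ...) {
  cat(sprintf("<pa_projection> %d detectors x %d bins -> %d x %d image (%d nonzeros)\n",
              x$det$n_points, length(x$times), x$ny, x$nx,
              length(x$M@x)))
  invisible(x)
}

#' Apply a projector to an image
#'
#' @param proj a [build_projection_matrix()] result.
#' @param img a [pa_grid()] (or matrix of matching size).
#' @return A `pa_signals` object with a `n_detectors x n_bins` value matrix.
#' @export
forward_apply <- function(proj, img) {
  v <- if (inherits(img, "pa_grid")) grid_vec(img) else as.vector(img)
  g <- as.vector(proj$M %*% v)
  pa_signals(t(matrix(g, length(proj$times), proj$det$n_points)),
             proj$det, proj$times)
}

# power-iteration estimate of ||M||_2 (deterministic start), cached
proj_norm <- function(proj, iters = 30L) {
  if (!is.null(proj$norm)) return(proj$norm)
  v <- rep(1, ncol(proj$M))
  v <- v / sqrt(sum(v^2))
  s <- 1
  for (k in seq_len(iters)) {
    w <- as.vector(Matrix::crossprod(proj$M, proj$M %*% v))
    s <- sqrt(sum(w^2))
    if (s == 0) return(1)
    v <- w / s
  }
  sqrt(s)
}

#' Signal sets
#'
#' Per-detector time series of the integrated quantity `g` (the
#' time-weighted cumulative pressure integral the linear forward model
#' predicts), stored as an `n_detectors x n_bins` matrix paired with its
#' geometry.
#'
#' @param values numeric matrix, one row per detector.
#' @param det the [detector_line()] the rows belong to.
#' @param times bin-centre times in seconds.
#' @export
pa_signals <- function(values, det, times) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)), nrow(values) == det$n_points,
            ncol(values) == length(times))
  structure(list(values = values, det = det, times = times),
            class = "pa_signals")
}

#' @exportS3Method
print.pa_signals <- function(x, ...) {
  cat(sprintf("<pa_signals> %d detectors x %d time bins, values in [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# signal matrix vectorised to match projector row order
signals_vec <- function(sig) as.vector(t(sig$values))

#' Simulate integrated signals from an analytic phantom
#'
#' Synthesizes `g` by applying an arc projector built on a grid
#' `supersample` times finer than the reconstruction raster, so the solver
#' never inverts the operator that generated its data (no inverse crime).
#'
#' @param spec a [pa_phantom()].
#' @param det a [detector_line()].
#' @param tg a [time_grid()].
#' @param supersample fine-grid refinement factor (>= 2).
#' @param nx reconstruction-grid pixel count the refinement is relative to.
#' @param downsample,max_bins,samples_per_pixel passed to the fine projector;
#'   defaults match [build_projection_matrix()] so the time bins line up
#'   with the solver's.
#' @return A `pa_signals` object.
#' @export
simulate_signals <- function(spec, det, tg, supersample = 2L, nx = 128L,
                             downsample = NULL, max_bins = 1024L,
                             samples_per_pixel = 4) {
  stopifnot(inherits(spec, "pa_phantom"))
  if (supersample < 2L) stop("supersample must be >= 2 to avoid the inverse crime")
  fine <- rasterize(spec, nx * supersample, nx * supersample, supersample = 1L)
  proj <- build_projection_matrix(fine, det, tg, downsample = downsample,
                                  max_bins = max_bins,
                                  samples_per_pixel = samples_per_pixel)
  forward_apply(proj, fine)
}

#' Integrated signal from raw pressure traces
#'
#' Converts detected pressure `p(r0, t)` into the integrated quantity
#' `g(r0, t) = (4 pi Cp t / beta) * integral_0^t p dt` via cumulative
#' trapezoidal integration along each trace.
#'
#' @param p `n_detectors x n_samples` pressure matrix sampled on `tg`'s raw
#'   time samples.
#' @param tg a [time_grid()].
#' @param det a [detector_line()].
#' @param Cp specific heat, J/(kg K).
#' @param beta_exp thermal (isobaric) expansion coefficient, 1/K.
#' @return A `pa_signals` object on the raw sample times.
#' @export
g_from_pressure <- function(p, tg, det, Cp = 4000, beta_exp = 4e-4) {
  p <- as.matrix(p)
  stopifnot(all(is.finite(p)), Cp > 0, beta_exp > 0,
            ncol(p) == tg$n_samples)
  tt <- time_samples(tg)
  dt <- 1 / tg$fs
  # cumulative trapezoid along rows
  n <- ncol(p)
  if (n > 1) {
    mids <- (p[, -1, drop = FALSE] + p[, -n, drop = FALSE]) / 2 * dt
    cum <- cbind(0, t(apply(mids, 1, cumsum)))
  } else cum <- matrix(0, nrow(p), 1)
  g <- sweep(cum, 2, 4 * pi * Cp * tt / beta_exp, "*")
  pa_signals(g, det, tt)
}

#' Add white Gaussian noise at a target SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise with variance
#' `mean(g^2) / 10^(snr_db/10)` (signal power over all samples).
#' Reproducible: the RNG state is set from `seed` and restored on exit.
#'
#' @param sig a [pa_signals()].
#' @param snr_db target signal-to-noise ratio in dB; `Inf` returns the input.
#' @param seed integer seed.
#' @return A `pa_signals` with noise added.
#' @export
add_noise <- function(sig, snr_db, seed = 1L) {
  stopifnot(inherits(sig, "pa_signals"))
  if (is.infinite(snr_db) && snr_db > 0) return(sig)
  power <- mean(sig$values^2)
  if (power == 0) stop("cannot set a finite SNR on an all-zero signal")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sd_n <- sqrt(power / 10^(snr_db / 10))
  sig$values <- sig$values +
    matrix(rnorm(length(sig$values), sd = sd_n),
           nrow(sig$values), ncol(sig$values))
  sig
}

#' Read / write signal sets as CSV
#'
#' One row per detector; the header row carries the bin-centre times in
#' seconds. Detector geometry is not stored: pass it back when reading.
#'
#' @param sig a [pa_signals()].
#' @param path file path.
#' @param det a [detector_line()] matching the stored rows.
#' @export
write_signals_csv <- function(sig, path) {
  stopifnot(inherits(sig, "pa_signals"))
  m <- sig$values
  colnames(m) <- sprintf("t=%.12g", sig$times)
  write.table(m, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(path, det) {
  m <- as.matrix(read.table(path, sep = ",", header = TRUE,
                            check.names = FALSE))
  times <- as.numeric(sub("^t=", "", colnames(m)))
  dimnames(m) <- NULL
  pa_signals(m, det, times)
}
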