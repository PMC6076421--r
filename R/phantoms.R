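#' Analytic ellipse phantoms
#'
#' Phantoms are ordered lists of ellipses whose intensities sum additively
#' where they overlap (the usual Shepp-Logan convention). All geometry is in
#' physical mm in the centred coordinate frame described in [pa_grid()].
#'
#' @param ellipses data frame with columns `x0`, `y0` (centre, mm), `a`, `b`
#'   (semi-axes, mm), `angle` (rotation in radians, counter-clockwise) and
#'   `intensity`.
#' @param extent physical width/height of the (square) phantom support in mm.
#' @return A `pa_phantom` object.
#' @export
pa_phantom <- function(ellipses, extent) {
  ellipses <- tibble::as_tibble(ellipses)
  needed <- c("x0", "y0", "a", "b", "angle", "intensity")
  if (!all(needed %in% names(ellipses)))
    stop("ellipses must have columns ", paste(needed, collapse = ", "))
  if (nrow(ellipses) > 0 && any(ellipses$a <= 0 | ellipses$b <= 0))
    stop("semi-axes must be strictly positive")
  if (!is.numeric(extent) || length(extent) != 1L || extent <= 0)
    stop("extent must be a positive scalar (mm)")
  ellipses$angle <- ellipses$angle %% (2 * pi)
  structure(list(ellipses = ellipses, extent = extent),
            class = "pa_phantom")
}

#' @exportS3Method
print.pa_phantom <- function(x, ...) {
  cat(sprintf("<pa_phantom> %d ellipse(s), extent %.4g mm\n",
              nrow(x$ellipses), x$extent))
  invisible(x)
}

# classic 10-ellipse Shepp-Logan table (original intensities, head pointing
# up, unit half-width frame), scaled by `half` mm
shepp_logan_table <- function(half) {
  t <- tibble::tibble(
    x0 = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0 = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.605, -0.605),
    a  = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b  = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    angle = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0) * pi / 180,
    intensity = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  )
  t$x0 <- t$x0 * half; t$y0 <- t$y0 * half
  t$a <- t$a * half;   t$b <- t$b * half
  t
}

#' Built-in phantoms
#'
#' `make_shepp_logan()` returns the standard 10-ellipse Shepp-Logan head with
#' its original (un-normalised) intensities, scaled to a 76.8 x 76.8 mm
#' support. `make_forbild()` returns an ellipse-only FORBILD-style head of
#' comparable complexity (12 nested ellipses: skull, brain, ventricles, eyes,
#' sinus and low-contrast lesions) at the same scale; the published FORBILD
#' head mixes non-ellipse primitives, so this is an approximation at matching
#' difficulty, not a pixel-level replica.
#'
#' @param extent support width in mm (default 76.8).
#' @return A [pa_phantom()].
#' @export
make_shepp_logan <- function(extent = 76.8) {
  pa_phantom(shepp_logan_table(extent / 2), extent = extent)
}

#' @rdname make_shepp_logan
#' @export
make_forbild <- function(extent = 76.8) {
  half <- extent / 2
  t <- tibble::tibble(
    x0 = c(0, 0, -0.17, 0.17, -0.25, 0.25, 0, 0.2, -0.2, 0, 0.05, -0.05),
    y0 = c(0, -0.01, 0.10, 0.10, -0.62, -0.62, -0.56, -0.25, -0.30,
           0.45, 0.66, 0.66),
    a  = c(0.72, 0.66, 0.09, 0.09, 0.08, 0.08, 0.10, 0.03, 0.05,
           0.18, 0.02, 0.02),
    b  = c(0.95, 0.88, 0.28, 0.28, 0.08, 0.08, 0.16, 0.03, 0.03,
           0.12, 0.02, 0.02),
    angle = c(0, 0, 15, -15, 0, 0, 0, 0, 30, 0, 0, 0) * pi / 180,
    intensity = c(1.8, -0.75, -0.25, -0.25, 0.45, 0.45, -0.40, 0.35, 0.30,
                  0.20, 0.40, 0.40)
  )
  t$x0 <- t$x0 * half; t$y0 <- t$y0 * half
  t$a <- t$a * half;   t$b <- t$b * half
  pa_phantom(t, extent = extent)
}

# analytic phantom evaluated at arbitrary point sets: x columns, y rows
eval_phantom <- function(spec, x, y) {
  out <- matrix(0, length(y), length(x))
  DX <- matrix(x, length(y), length(x), byrow = TRUE)
  DY <- matrix(y, length(y), length(x))
  for (k in seq_len(nrow(spec$ellipses))) {
    e <- spec$ellipses[k, ]
    ca <- cos(e$angle); sa <- sin(e$angle)
    u <- (ca * (DX - e$x0) + sa * (DY - e$y0)) / e$a
    v <- (-sa * (DX - e$x0) + ca * (DY - e$y0)) / e$b
    out <- out + e$intensity * (u * u + v * v <= 1)
  }
  out
}

#' Rasterize a phantom onto an image grid
#'
#' Each pixel takes the mean of the analytic phantom over a `supersample` x
#' `supersample` lattice of sub-points inside the pixel (`supersample = 1`
#' samples the pixel centre). Deterministic; linear in the ellipse
#' intensities.
#'
#' @param spec a [pa_phantom()].
#' @param nx,ny pixel counts (>= 2).
#' @param supersample sub-points per pixel edge (>= 1).
#' @return A [pa_grid()] with `pixel_size = extent / nx`.
#' @export
rasterize <- function(spec, nx, ny = nx, supersample = 1L) {
  stopifnot(inherits(spec, "pa_phantom"))
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  if (supersample < 1L) stop("supersample must be >= 1")
  px <- spec$extent / nx
  fx <- nx * supersample
  fy <- ny * supersample
  fpx <- spec$extent / fx
  x <- -spec$extent / 2 + (seq_len(fx) - 0.5) * fpx
  y <- spec$extent / 2 - (seq_len(fy) - 0.5) * fpx
  fine <- eval_phantom(spec, x, y)
  if (supersample > 1L) {
    # block-average supersample x supersample cells
    fine <- block_mean(fine, supersample)
  }
  pa_grid(fine, pixel_size = px)
}

block_mean <- function(m, s) {
  ny <- nrow(m) / s
  nx <- ncol(m) / s
  dim(m) <- c(s, ny, s, nx)
  out <- apply(m, c(2, 4), mean)
  matrix(out, ny, nx)
}

#' Phantom specs as YAML text
#'
#' Serialize a phantom to (and from) a plain-text YAML mapping with one entry
#' per ellipse: `center` (mm), `axes` (semi-axes, mm), `angle_deg`,
#' `intensity`, plus the overall `extent_mm`.
#'
#' @param spec a [pa_phantom()].
#' @param path file path; for `phantom_from_yaml` an existing file.
#' @export
phantom_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "pa_phantom"))
  ell <- lapply(seq_len(nrow(spec$ellipses)), function(k) {
    e <- spec$ellipses[k, ]
    list(center = c(e$x0, e$y0), axes = c(e$a, e$b),
         angle_deg = e$angle * 180 / pi, intensity = e$intensity)
  })
  yaml::write_yaml(list(extent_mm = spec$extent, ellipses = ell), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname phantom_to_yaml
#' @export
phantom_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  ell <- do.call(rbind, lapply(cfg$ellipses, function(e) {
    data.frame(x0 = e$center[1], y0 = e$center[2], a = e$axes[1],
               b = e$axes[2], angle = e$angle_deg * pi / 180,
               intensity = e$intensity)
  }))
  if (is.null(ell))
    ell <- data.frame(x0 = numeric(), y0 = numeric(), a = numeric(),
                      b = numeric(), angle = numeric(), intensity = numeric())
  pa_phantom(ell, extent = cfg$extent_mm)
}
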