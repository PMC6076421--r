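#' Nonlocal patch-weight configuration
#'
#' Parameters of the steering-kernel similarity search that builds the
#' nonlocal operator `H`.
#'
#' @param patch_radius patch half-width in pixels (patch is
#'   `(2 * patch_radius + 1)^2`).
#' @param h global smoothing (bandwidth) parameter of the weight kernel, in
#'   pixel units. The effective spatial footprint at a pixel is `h * mu`
#'   with `mu` the local density from the structure tensors; `mu` is far
#'   below one in flat regions, so useful values of `h` are large.
#' @param patch_h intensity bandwidth of the patch dissimilarity term, on
#'   the unit-peak scale the image is normalised to before the search.
#' @param T similarity threshold in (0, 1), applied after per-row max
#'   normalisation of the raw weights.
#' @param tensor_smoothing Gaussian sigma (pixels) smoothing the gradient
#'   outer products into structure tensors.
#' @param max_neighbors cap on the row support of `H`.
#' @param candidate_stride subsampling stride of the whole-image candidate
#'   search.
#' @param window_radius half-width of the exhaustive local search window.
#' @param use_patch_term include the patch mean-squared-difference term in
#'   the weight exponent (`FALSE` reduces to pure centre-displacement
#'   weights).
#' @param rebuild_every rebuild `H` from the current iterate every this many
#'   solver iterations.
#' @return A `patch_config` list.
#' @export
patch_config <- function(patch_radius = 1L, h = 150, patch_h = 0.12,
                         T = 0.65,
                         tensor_smoothing = 1.5, max_neighbors = 24L,
                         candidate_stride = 2L, window_radius = 5L,
                         use_patch_term = TRUE, rebuild_every = 1L) {
  stopifnot(patch_radius >= 1L, h > 0, patch_h > 0, T > 0, T < 1,
            tensor_smoothing > 0,
            max_neighbors >= 1L, candidate_stride >= 1L, window_radius >= 0L,
            rebuild_every >= 1L)
  structure(list(patch_radius = as.integer(patch_radius), h = h,
                 patch_h = patch_h, T = T,
                 tensor_smoothing = tensor_smoothing,
                 max_neighbors = as.integer(max_neighbors),
                 candidate_stride = as.integer(candidate_stride),
                 window_radius = as.integer(window_radius),
                 use_patch_term = isTRUE(use_patch_term),
                 rebuild_every = as.integer(rebuild_every)),
            class = "patch_config")
}

# separable Gaussian smoothing with replicate (edge-clamped) boundary
gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_gaussian <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  ny <- nrow(m); nx <- ncol(m)
  # rows (vertical) pass
  out <- matrix(0, ny, nx)
  for (t in seq_along(k)) {
    sh <- t - r - 1L
    idx <- pmin(pmax(seq_len(ny) + sh, 1L), ny)
    out <- out + k[t] * m[idx, , drop = FALSE]
  }
  m <- out
  out <- matrix(0, ny, nx)
  for (t in seq_along(k)) {
    sh <- t - r - 1L
    idx <- pmin(pmax(seq_len(nx) + sh, 1L), nx)
    out <- out + k[t] * m[, idx, drop = FALSE]
  }
  out
}

# central-difference gradients in pixel-index coordinates (gx along columns,
# gy along rows), replicate boundary
image_gradients <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  right <- m[, pmin(seq_len(nx) + 1L, nx), drop = FALSE]
  left  <- m[, pmax(seq_len(nx) - 1L, 1L), drop = FALSE]
  down  <- m[pmin(seq_len(ny) + 1L, ny), , drop = FALSE]
  up    <- m[pmax(seq_len(ny) - 1L, 1L), , drop = FALSE]
  list(gx = (right - left) / 2, gy = (down - up) / 2)
}

#' Steering structure tensors
#'
#' Builds the per-pixel direction-adaptive tensor field driving the weight
#' function: gradient outer products are Gaussian-smoothed into a tensor
#' `G = U diag(l1, l2) U'` per pixel, which is eigen-regularised into the
#' unit-determinant steering matrix
#' `S = U diag((l1+e)/(l2+e), (l2+e)/(l1+e)) U'` with
#' `e = 1e-3 * max(l1)` taken over the whole field, and the local sample
#' density `mu = (l1 l2 + e^2)^(1/4)`. On a perfectly flat image the field
#' degenerates to isotropic unit tensors with `mu = 1`, so weights reduce to
#' isotropic Gaussians.
#'
#' @param A a [pa_grid()] or numeric matrix.
#' @param cfg a [patch_config()].
#' @return A `structure_tensors` list with matrices `Sxx`, `Sxy`, `Syy`,
#'   `mu`, `lambda1`, `lambda2`.
#' @export
compute_structure_tensors <- function(A, cfg = patch_config()) {
  m <- if (inherits(A, "pa_grid")) A$values else as.matrix(A)
  if (!all(is.finite(m))) stop("image must be finite")
  g <- image_gradients(m)
  J11 <- smooth_gaussian(g$gx * g$gx, cfg$tensor_smoothing)
  J12 <- smooth_gaussian(g$gx * g$gy, cfg$tensor_smoothing)
  J22 <- smooth_gaussian(g$gy * g$gy, cfg$tensor_smoothing)
  tr2 <- (J11 + J22) / 2
  disc <- sqrt(pmax(((J11 - J22) / 2)^2 + J12^2, 0))
  l1 <- tr2 + disc
  l2 <- pmax(tr2 - disc, 0)
  eps <- 1e-3 * max(l1)
  if (eps < 1e-300) {       # flat image: isotropic fallback
    one <- matrix(1, nrow(m), ncol(m))
    zero <- matrix(0, nrow(m), ncol(m))
    return(structure(list(Sxx = one, Sxy = zero, Syy = one, mu = one,
                          lambda1 = l1, lambda2 = l2),
                     class = "structure_tensors"))
  }
  rho <- (l1 + eps) / (l2 + eps)
  # unit eigenvector (cx, cy) of the dominant eigenvalue l1
  vx <- ifelse(abs(J12) > 1e-14 * pmax(l1, 1e-300), J12, ifelse(J11 >= J22, 1, 0))
  vy <- ifelse(abs(J12) > 1e-14 * pmax(l1, 1e-300), l1 - J11, ifelse(J11 >= J22, 0, 1))
  nrm <- sqrt(vx^2 + vy^2)
  nrm[nrm == 0] <- 1
  cx <- vx / nrm; cy <- vy / nrm
  Sxx <- rho * cx^2 + cy^2 / rho
  Syy <- rho * cy^2 + cx^2 / rho
  Sxy <- (rho - 1 / rho) * cx * cy
  mu <- (l1 * l2 + eps^2)^0.25
  structure(list(Sxx = Sxx, Sxy = Sxy, Syy = Syy, mu = mu,
                 lambda1 = l1, lambda2 = l2),
            class = "structure_tensors")
}

#' Direction-adaptive weight between two pixels
#'
#' Evaluates the steering-kernel weight
#' `sqrt(det S_j) / (2 pi h^2 mu_j^2) * exp(-d' S_j d / (2 h^2 mu_j^2))`
#' for the pixel-coordinate displacement `d = x_i - x_j` (centre
#' displacement only; the operator builder adds the patch-content term on
#' top of this).
#'
#' @param i,j linear pixel indices (column-major).
#' @param tensors a [compute_structure_tensors()] field.
#' @param cfg a [patch_config()] (only `h` is used).
#' @return The scalar weight.
#' @export
patch_weight <- function(i, j, tensors, cfg = patch_config()) {
  ny <- nrow(tensors$mu)
  ri <- (i - 1L) %% ny; ci <- (i - 1L) %/% ny
  rj <- (j - 1L) %% ny; cj <- (j - 1L) %/% ny
  dc <- ci - cj; dr <- ri - rj
  Sxx <- tensors$Sxx[j]; Sxy <- tensors$Sxy[j]; Syy <- tensors$Syy[j]
  mu <- tensors$mu[j]
  dets <- Sxx * Syy - Sxy^2
  denom <- 2 * cfg$h^2 * mu^2
  q <- (Sxx * dc^2 + 2 * Sxy * dc * dr + Syy * dr^2) / denom
  sqrt(max(dets, 0)) / (pi * denom) * exp(-q)
}

#' Build the sparse nonlocal operator H
#'
#' For every pixel, candidate neighbours are the whole image subsampled at
#' `candidate_stride` plus an exhaustive `(2*window_radius+1)^2` local
#' window. Raw steering-kernel weights (optionally patch-content aware) are
#' max-normalised per row, screened at threshold `T`, capped at
#' `max_neighbors`, and renormalised to sum to one, with the pixel itself
#' always kept — so `H` is row-stochastic and `H %*% constant = constant`
#' exactly. The image is rescaled to unit peak before the tensor and weight
#' computation so the operator is invariant to the iterate's overall scale.
#'
#' @param A a [pa_grid()] or numeric matrix (typically the current iterate).
#' @param cfg a [patch_config()].
#' @return A `pa_nonlocal` object holding the `dgCMatrix` `H`.
#' @export
build_nonlocal_operator <- function(A, cfg = patch_config()) {
  m <- if (inherits(A, "pa_grid")) A$values else as.matrix(A)
  if (!all(is.finite(m))) stop("image must be finite")
  peak <- max(abs(m))
  if (peak > 0) m <- m / peak
  tens <- compute_structure_tensors(m, cfg)
  pr <- cfg$patch_radius
  off <- seq(-pr, pr)
  pk <- exp(-outer(off^2, off^2, "+") / (2 * pr^2))
  pk <- as.vector(pk / sum(pk))         # Gaussian patch window, row-fastest
  tr <- nonlocal_triplets(m, tens$Sxx, tens$Sxy, tens$Syy, tens$mu,
                          cfg$h, cfg$patch_h, cfg$T, pr, cfg$candidate_stride,
                          cfg$window_radius, cfg$max_neighbors,
                          cfg$use_patch_term, pk)
  n <- length(m)
  H <- Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$x,
                            dims = c(n, n))
  structure(list(H = H, nx = ncol(m), ny = nrow(m), cfg = cfg),
            class = "pa_nonlocal")
}

#' @exportS3Method
print.pa_nonlocal <- function(x, ...) {
  cat(sprintf("<pa_nonlocal> %d x %d, mean row support %.1f\n",
              nrow(x$H), ncol(x$H), length(x$H@x) / nrow(x$H)))
  invisible(x)
}

#' Export H as coordinate-format sparse text
#'
#' Writes the operator in MatrixMarket coordinate format for inspection.
#'
#' @param op a [build_nonlocal_operator()] result.
#' @param path file path.
#' @export
write_nonlocal_mm <- function(op, path) {
  stopifnot(inherits(op, "pa_nonlocal"))
  Matrix::writeMM(op$H, path)
  invisible(path)
}
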