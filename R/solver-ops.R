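# -- discrete gradient machinery --------------------------------------------
#
# Backward differences with periodic wrap (row m - row m-1, col n - col n-1),
# the discretisation the Fourier-domain image update diagonalises. Fields of
# per-pixel 2-vectors are lists with components $x (column differences) and
# $y (row differences), each an ny x nx matrix.

diff_back <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  list(x = m - m[, c(nx, seq_len(nx - 1L)), drop = FALSE],
       y = m - m[c(ny, seq_len(ny - 1L)), , drop = FALSE])
}

# adjoint of diff_back: D' u = Dx' ux + Dy' uy (negative forward difference)
diff_back_adjoint <- function(u) {
  ux <- u$x; uy <- u$y
  ny <- nrow(ux); nx <- ncol(ux)
  (ux - ux[, c(seq_len(nx - 1L) + 1L, 1L), drop = FALSE]) +
    (uy - uy[c(seq_len(ny - 1L) + 1L, 1L), , drop = FALSE])
}

vfield_zero <- function(ny, nx) list(x = matrix(0, ny, nx),
                                     y = matrix(0, ny, nx))

vfield_norm2 <- function(u) sum(u$x^2) + sum(u$y^2)

#' Isotropic total variation of an image
#'
#' `TV(A) = sum_mn sqrt((A[m,n]-A[m-1,n])^2 + (A[m,n]-A[m,n-1])^2)`.
#' With the `"zero"` boundary rule differences across the image border are
#' zero (the literal finite sum); `"periodic"` wraps, matching the
#' discretisation used inside the splitting solver.
#'
#' @param A a [pa_grid()] or numeric matrix.
#' @param boundary `"zero"` or `"periodic"`.
#' @return The scalar TV value.
#' @export
tv_value <- function(A, boundary = c("zero", "periodic")) {
  boundary <- match.arg(boundary)
  m <- if (inherits(A, "pa_grid")) A$values else as.matrix(A)
  d <- diff_back(m)
  if (boundary == "zero") {
    d$x[, 1] <- 0
    d$y[1, ] <- 0
  }
  sum(sqrt(d$x^2 + d$y^2))
}

#' Shrinkage (soft-threshold) update of the gradient surrogate
#'
#' Per-pixel exact minimiser of
#' `|u|_2 + |u - a1|_2^2 + (sigma_n/alpha) |u - a2|_2^2`
#' over 2-vectors `u`: with `c = 2 (1 + sigma_n/alpha)` and
#' `v = 2 a1 + 2 (sigma_n/alpha) a2`, the solution is
#' `u = max(|v| - 1, 0)/c * v/|v|` (and `u = 0` where `v = 0`).
#' In the solver `a1 = D A^n + b^n` and `a2 = u^n`.
#'
#' @param a1,a2 2-vector fields (`list(x =, y =)` of matrices).
#' @param alpha TV weight (> 0).
#' @param sigma_n current step scalar (> 0).
#' @return The updated 2-vector field.
#' @export
shrink_step <- function(a1, a2, alpha, sigma_n) {
  stopifnot(alpha > 0, sigma_n > 0)
  s <- sigma_n / alpha
  cc <- 2 * (1 + s)
  vx <- 2 * a1$x + 2 * s * a2$x
  vy <- 2 * a1$y + 2 * s * a2$y
  mag <- sqrt(vx^2 + vy^2)
  scale <- ifelse(mag > 0, pmax(mag - 1, 0) / (cc * mag), 0)
  list(x = scale * vx, y = scale * vy)
}

# -- stacked operator K = [M ; sqrt(beta) (I - H)] ---------------------------

#' Stack the data and patch operators
#'
#' Builds the joint operator `K = [M ; sqrt(beta) (I - H)]` and stacked data
#' `g~ = [g ; 0]` that turn the patch-TV objective into a standard
#' least-squares-plus-TV problem. The square root keeps the realised
#' quadratic penalty exactly `beta * ||(I - H) A||^2`.
#'
#' @param M sparse data operator (rows = detector-time samples).
#' @param g numeric data vector matching `M`'s rows.
#' @param H row-stochastic nonlocal operator, or `NULL` for no patch block
#'   (`beta = 0`).
#' @param beta patch-penalty weight (>= 0).
#' @return A `pa_stacked` object.
#' @export
stacked_operator <- function(M, g, H = NULL, beta = 0) {
  stopifnot(beta >= 0, length(g) == nrow(M))
  if (beta > 0 && is.null(H)) stop("beta > 0 requires H")
  structure(list(M = M, g = g, H = if (beta > 0) H else NULL,
                 sqrt_beta = sqrt(beta), n = ncol(M)),
            class = "pa_stacked")
}

# K applied to a pixel vector; returns list(data, patch)
stacked_apply <- function(K, a) {
  dat <- as.vector(K$M %*% a)
  pat <- if (!is.null(K$H)) K$sqrt_beta * (a - as.vector(K$H %*% a)) else NULL
  list(data = dat, patch = pat)
}

# K'(K a - g~) as a pixel vector
stacked_grad <- function(K, a) {
  r <- as.vector(K$M %*% a) - K$g
  out <- as.vector(Matrix::crossprod(K$M, r))
  if (!is.null(K$H)) {
    rp <- K$sqrt_beta * (a - as.vector(K$H %*% a))
    out <- out + K$sqrt_beta * (rp - as.vector(Matrix::crossprod(K$H, rp)))
  }
  out
}

# ||K a - g~||^2
stacked_resid2 <- function(K, a) {
  ka <- stacked_apply(K, a)
  sum((ka$data - K$g)^2) + if (is.null(ka$patch)) 0 else sum(ka$patch^2)
}

# ||K v||^2 (for the BB numerator)
stacked_norm2 <- function(K, v) {
  ka <- stacked_apply(K, v)
  sum(ka$data^2) + if (is.null(ka$patch)) 0 else sum(ka$patch^2)
}

# -- Fourier image update ----------------------------------------------------

# eigenvalues of D'D for periodic backward differences on an ny x nx grid
laplacian_symbol <- function(ny, nx) {
  wy <- 2 - 2 * cos(2 * pi * (seq_len(ny) - 1L) / ny)
  wx <- 2 - 2 * cos(2 * pi * (seq_len(nx) - 1L) / nx)
  outer(wy, rep(1, nx)) + outer(rep(1, ny), wx)
}

#' Exact quadratic image update via the FFT
#'
#' Solves `(alpha D'D + sigma_n I) A = alpha D'u + sigma_n A^n - K'(K A^n - g~)`
#' exactly by pointwise division in the Fourier domain (the periodic
#' difference operator diagonalises under the 2D DFT; the denominator is
#' bounded below by `sigma_n > 0`).
#'
#' @param A_n current image matrix.
#' @param u_next 2-vector field from [shrink_step()].
#' @param alpha TV weight (>= 0; `alpha = 0` reduces to the plain gradient
#'   step `A^n - sigma_n^{-1} K'(K A^n - g~)`).
#' @param sigma_n step scalar (> 0).
#' @param K a [stacked_operator()].
#' @return The updated image matrix.
#' @export
image_update <- function(A_n, u_next, alpha, sigma_n, K) {
  stopifnot(sigma_n > 0, alpha >= 0)
  ny <- nrow(A_n); nx <- ncol(A_n)
  grad <- matrix(stacked_grad(K, as.vector(A_n)), ny, nx)
  rhs <- sigma_n * A_n - grad
  if (alpha > 0) rhs <- rhs + alpha * diff_back_adjoint(u_next)
  denom <- alpha * laplacian_symbol(ny, nx) + sigma_n
  Re(fft(fft(rhs) / denom, inverse = TRUE)) / (ny * nx)
}

#' Bregman / Barzilai-Borwein bookkeeping
#'
#' Updates the TV step parameter `b^{n+1} = b^n - (u^{n+1} - D A^{n+1})` and
#' the Barzilai-Borwein step scalar
#' `sigma_{n+1} = ||K (A^{n+1}-A^n)||^2 / (||u^{n+1}-u^n||^2 + ||A^{n+1}-A^n||^2)`,
#' keeping `sigma_n` unchanged when the denominator vanishes (no change in
#' the iterates).
#'
#' @param A_n,A_next previous and updated image matrices.
#' @param u_n,u_next previous and updated gradient surrogates.
#' @param b_n current step-parameter field.
#' @param sigma_n current step scalar.
#' @param K a [stacked_operator()].
#' @return `list(b = b_next, sigma = sigma_next)`.
#' @export
bb_step_update <- function(A_n, A_next, u_n, u_next, b_n, sigma_n, K) {
  dA <- A_next - A_n
  d_next <- diff_back(A_next)
  b_next <- list(x = b_n$x - (u_next$x - d_next$x),
                 y = b_n$y - (u_next$y - d_next$y))
  den <- vfield_norm2(list(x = u_next$x - u_n$x, y = u_next$y - u_n$y)) +
    sum(dA^2)
  sigma_next <- if (den > 0) stacked_norm2(K, as.vector(dA)) / den else sigma_n
  if (!is.finite(sigma_next) || sigma_next <= 0) sigma_next <- sigma_n
  list(b = b_next, sigma = sigma_next)
}

#' Relative-change stopping rule
#'
#' True when `||u^n - u^{n-1}|| / ||u^n|| < epsilon`; an all-zero pair is
#' converged, an all-zero `u^n` with nonzero `u^{n-1}` is not (ratio 1).
#'
#' @param u_n,u_prev 2-vector fields.
#' @param epsilon tolerance (> 0).
#' @return Logical.
#' @export
stopping_check <- function(u_n, u_prev, epsilon) {
  stopifnot(epsilon > 0)
  num <- sqrt(vfield_norm2(list(x = u_n$x - u_prev$x, y = u_n$y - u_prev$y)))
  den <- sqrt(vfield_norm2(u_n))
  if (den == 0) return(num == 0)
  (num / den) < epsilon
}
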