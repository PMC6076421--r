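#' Solver parameters
#'
#' @param alpha TV weight (>= 0).
#' @param beta nonlocal-patch weight (>= 0).
#' @param T patch similarity threshold, forwarded to the [patch_config()]
#'   (values >= 1 disable screening, reducing `H` to the identity).
#' @param max_iters iteration budget (10 in the bundled study configurations).
#' @param epsilon relative-change stopping tolerance on the gradient
#'   surrogate.
#' @param sigma0 initial step scalar of the splitting scheme.
#' @param gd_step relative step of the fixed-step TV gradient-descent
#'   baseline (on the spectrally normalised operator).
#' @param tv_smooth_eps smoothing of the TV gradient in the baseline.
#' @return A `solver_params` list.
#' @export
solver_params <- function(alpha = 0.4, beta = 0.35, T = 0.65,
                          max_iters = 10L, epsilon = 1e-4, sigma0 = 1,
                          gd_step = 0.25, tv_smooth_eps = 1e-8) {
  stopifnot(alpha >= 0, beta >= 0, max_iters >= 1L, epsilon > 0, sigma0 > 0,
            gd_step > 0, tv_smooth_eps > 0)
  structure(list(alpha = alpha, beta = beta, T = T,
                 max_iters = as.integer(max_iters), epsilon = epsilon,
                 sigma0 = sigma0, gd_step = gd_step,
                 tv_smooth_eps = tv_smooth_eps),
            class = "solver_params")
}

recon_grid <- function(proj, v) {
  pa_grid(matrix(v, proj$ny, proj$nx), pixel_size = proj$pixel_size)
}

new_recon <- function(proj, A, d, obj, iters, converged, solver, params,
                      runtime) {
  structure(list(image = recon_grid(proj, as.vector(A)),
                 d_per_iter = d, objective_per_iter = obj,
                 iters_run = iters, converged = converged, solver = solver,
                 params = params, runtime_s = runtime),
            class = "pa_recon")
}

#' @exportS3Method
print.pa_recon <- function(x, ...) {
  cat(sprintf("<pa_recon> %s: %d iteration(s)%s, %.2fs\n", x$solver,
              x$iters_run, if (x$converged) " (converged)" else "",
              x$runtime_s))
  if (length(x$d_per_iter))
    cat(sprintf("  final distance d = %.4g\n",
                x$d_per_iter[length(x$d_per_iter)]))
  invisible(x)
}

# shared preamble: vectorised data and spectrally normalised operator, so
# the regularisation weights are comparable across geometries
solver_setup <- function(g, proj) {
  stopifnot(inherits(g, "pa_signals"), inherits(proj, "pa_projection"))
  gvec <- signals_vec(g)
  if (length(gvec) != nrow(proj$M))
    stop("signal set and projector disagree on detectors/time bins")
  s <- proj_norm(proj)
  list(M = proj$M / s, g = gvec / s)
}

maybe_d <- function(A, reference) {
  if (is.null(reference)) return(numeric(0))
  R <- if (inherits(reference, "pa_grid")) reference$values else reference
  sqrt(sum((A - R)^2) / sum(R^2))
}

# H built from an image matrix with the solver's T spliced into the config
solver_H <- function(A, patch_cfg, T) {
  cfg <- patch_cfg
  cfg$T <- T
  build_nonlocal_operator(A, cfg)$H
}

#' Patch-TV reconstruction
#'
#' Minimises
#' `||M A - g||^2 + alpha * TV(A) + beta * ||(I - H) A||^2`
#' by variable splitting with Barzilai-Borwein steps: per iteration the
#' nonlocal operator `H` is (re)built from the current iterate, the
#' gradient surrogate is updated by the closed-form shrinkage
#' ([shrink_step()]), the image by the exact Fourier-domain quadratic solve
#' ([image_update()]), and the Bregman field and step scalar by
#' [bb_step_update()], until the relative change of the surrogate falls
#' below `epsilon` or `max_iters` is reached. The first `H` is built from
#' the normalised backprojection `M' g` (the zero initial image has no
#' structure to weight). With `beta = 0` (or `T >= 1`) the patch block
#' vanishes and the solver reduces to the TV-only splitting scheme.
#'
#' @param g a [pa_signals()] set.
#' @param proj the matching [build_projection_matrix()] operator.
#' @param params a [solver_params()].
#' @param patch_cfg a [patch_config()]; its `T` is overridden by
#'   `params$T`.
#' @param reference optional ground-truth [pa_grid()]: when given, the
#'   relative distance `d` to it is recorded every iteration.
#' @param verbose print per-iteration diagnostics.
#' @return A `pa_recon` object.
#' @export
patch_tv_reconstruct <- function(g, proj, params = solver_params(),
                                 patch_cfg = patch_config(),
                                 reference = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  su <- solver_setup(g, proj)
  ny <- proj$ny; nx <- proj$nx
  use_patch <- params$beta > 0 && params$T < 1
  A <- matrix(0, ny, nx)
  u <- vfield_zero(ny, nx)
  b <- vfield_zero(ny, nx)
  sigma <- params$sigma0
  H <- NULL
  if (use_patch) {
    bp <- matrix(as.vector(Matrix::crossprod(su$M, su$g)), ny, nx)
    H <- solver_H(bp, patch_cfg, params$T)
  }
  d_hist <- numeric(0)
  obj_hist <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (n in seq_len(params$max_iters)) {
    if (use_patch && n > 1L && (n - 1L) %% patch_cfg$rebuild_every == 0L)
      H <- solver_H(A, patch_cfg, params$T)
    K <- stacked_operator(su$M, su$g, H, if (use_patch) params$beta else 0)
    if (params$alpha > 0) {
      dA <- diff_back(A)
      a1 <- list(x = dA$x + b$x, y = dA$y + b$y)
      u_next <- shrink_step(a1, u, params$alpha, sigma)
    } else {
      u_next <- vfield_zero(ny, nx)
    }
    A_next <- image_update(A, u_next, params$alpha, sigma, K)
    if (!all(is.finite(A_next)))
      stop(sprintf("iterate diverged (non-finite values) at iteration %d; sigma = %.3g",
                   n, sigma))
    upd <- bb_step_update(A, A_next, u, u_next, b, sigma, K)
    iters <- n
    if (!is.null(reference)) d_hist[n] <- maybe_d(A_next, reference)
    dAn <- diff_back(A_next)
    obj_hist[n] <- stacked_resid2(K, as.vector(A_next)) +
      params$alpha * sum(sqrt(dAn$x^2 + dAn$y^2))
    if (verbose)
      message(sprintf("iter %2d: obj %.6g sigma %.3g%s", n, obj_hist[n],
                      sigma,
                      if (length(d_hist)) sprintf(" d %.4g", d_hist[n]) else ""))
    # the rule compares two computed surrogates; at n = 1 only the
    # initialisation u^0 = 0 exists, so the check starts at n = 2. Early
    # iterations can leave the surrogate pinned at zero (shrinkage dead
    # zone) while the image still moves; that state is not convergence.
    u_live <- vfield_norm2(u_next) > 0 || sum((A_next - A)^2) == 0
    converged <- n > 1L && u_live && stopping_check(u_next, u, params$epsilon)
    A <- A_next; u <- u_next; b <- upd$b; sigma <- upd$sigma
    if (converged) break
  }
  new_recon(proj, A, d_hist, obj_hist, iters, converged, "patch_tv", params,
            proc.time()[["elapsed"]] - t0)
}

# smoothed-TV gradient: D'( DA / sqrt(|DA|^2 + eps) )
tv_smooth_grad <- function(A, eps) {
  d <- diff_back(A)
  mag <- sqrt(d$x^2 + d$y^2 + eps)
  diff_back_adjoint(list(x = d$x / mag, y = d$y / mag))
}

#' Gradient-descent TV baseline
#'
#' Fixed-step gradient descent on
#' `||M A - g||^2 + alpha * TV_eps(A)` with an `eps`-smoothed TV gradient —
#' a simplified stand-in for classical gradient-descent TV reconstruction.
#' The step is `gd_step / (2 ||M||^2)` on the normalised operator, which
#' guarantees descent of the data term.
#'
#' @inheritParams patch_tv_reconstruct
#' @return A `pa_recon` object.
#' @export
tv_gd_reconstruct <- function(g, proj, params = solver_params(),
                              reference = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  su <- solver_setup(g, proj)
  ny <- proj$ny; nx <- proj$nx
  A <- matrix(0, ny, nx)
  tau <- params$gd_step / 2      # ||M|| = 1 after normalisation
  d_hist <- numeric(0)
  obj_hist <- numeric(0)
  for (n in seq_len(params$max_iters)) {
    r <- as.vector(su$M %*% as.vector(A)) - su$g
    grad <- 2 * matrix(as.vector(Matrix::crossprod(su$M, r)), ny, nx)
    if (params$alpha > 0)
      grad <- grad + params$alpha * tv_smooth_grad(A, params$tv_smooth_eps)
    A <- A - tau * grad
    if (!all(is.finite(A)))
      stop(sprintf("iterate diverged at iteration %d", n))
    if (!is.null(reference)) d_hist[n] <- maybe_d(A, reference)
    d <- diff_back(A)
    obj_hist[n] <- sum((as.vector(su$M %*% as.vector(A)) - su$g)^2) +
      params$alpha * sum(sqrt(d$x^2 + d$y^2 + params$tv_smooth_eps))
    if (verbose) message(sprintf("iter %2d: obj %.6g", n, obj_hist[n]))
  }
  new_recon(proj, A, d_hist, obj_hist, params$max_iters, FALSE, "tv_gd",
            params, proc.time()[["elapsed"]] - t0)
}

#' Patch-only regularized baseline
#'
#' Minimises `||M A - g||^2 + beta * ||(I - H) A||^2` by Barzilai-Borwein
#' gradient descent (no TV term, no splitting variables), rebuilding `H`
#' from the current iterate on the same schedule as [patch_tv_reconstruct()].
#'
#' @inheritParams patch_tv_reconstruct
#' @return A `pa_recon` object.
#' @export
patch_re_reconstruct <- function(g, proj, params = solver_params(),
                                 patch_cfg = patch_config(),
                                 reference = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  su <- solver_setup(g, proj)
  ny <- proj$ny; nx <- proj$nx
  use_patch <- params$beta > 0 && params$T < 1
  A <- matrix(0, ny, nx)
  H <- NULL
  if (use_patch) {
    bp <- matrix(as.vector(Matrix::crossprod(su$M, su$g)), ny, nx)
    H <- solver_H(bp, patch_cfg, params$T)
  }
  grad_fn <- function(A, K) 2 * matrix(stacked_grad(K, as.vector(A)), ny, nx)
  tau <- 1 / (2 * (1 + if (use_patch) params$beta else 0))
  d_hist <- numeric(0)
  obj_hist <- numeric(0)
  A_prev <- NULL
  g_prev <- NULL
  for (n in seq_len(params$max_iters)) {
    if (use_patch && n > 1L && (n - 1L) %% patch_cfg$rebuild_every == 0L)
      H <- solver_H(A, patch_cfg, params$T)
    K <- stacked_operator(su$M, su$g, H, if (use_patch) params$beta else 0)
    grad <- grad_fn(A, K)
    if (n > 1L) {
      dA <- A - A_prev
      dg <- grad - g_prev
      den <- sum(dA * dg)
      if (den > 0) tau <- sum(dA * dA) / den
    }
    A_prev <- A
    g_prev <- grad
    A <- A - tau * grad
    if (!all(is.finite(A)))
      stop(sprintf("iterate diverged at iteration %d", n))
    if (!is.null(reference)) d_hist[n] <- maybe_d(A, reference)
    obj_hist[n] <- stacked_resid2(K, as.vector(A))
    if (verbose) message(sprintf("iter %2d: obj %.6g tau %.3g", n,
                                 obj_hist[n], tau))
  }
  new_recon(proj, A, d_hist, obj_hist, params$max_iters, FALSE, "patch_re",
            params, proc.time()[["elapsed"]] - t0)
}

#' Backprojection baseline
#'
#' The adjoint of the forward operator applied to the data, scaled by the
#' least-squares coefficient fitting `c * M M' g` to `g`. Used as the
#' initial surface for the nonlocal weights and as the crudest baseline.
#'
#' @inheritParams patch_tv_reconstruct
#' @return A `pa_recon` object (one "iteration").
#' @export
backproject <- function(g, proj, reference = NULL) {
  t0 <- proc.time()[["elapsed"]]
  su <- solver_setup(g, proj)
  a <- as.vector(Matrix::crossprod(su$M, su$g))
  ma <- as.vector(su$M %*% a)
  den <- sum(ma^2)
  cc <- if (den > 0) sum(ma * su$g) / den else 0
  A <- matrix(cc * a, proj$ny, proj$nx)
  d <- maybe_d(A, reference)
  new_recon(proj, A, d, sum((cc * ma - su$g)^2), 1L, FALSE,
            "backprojection", NULL, proc.time()[["elapsed"]] - t0)
}
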