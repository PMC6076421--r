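#' Tidy a reconstruction's iteration history
#'
#' One row per iteration with the objective value and (when a reference was
#' supplied) the relative distance `d`.
#'
#' @param x a `pa_recon`.
#' @param ... unused.
#' @return A tibble with columns `solver`, `iteration`, `objective`, `d`.
#' @export
tidy.pa_recon <- function(x, ...) {
  n <- x$iters_run
  tibble::tibble(
    solver = x$solver,
    iteration = seq_len(n),
    objective = x$objective_per_iter[seq_len(n)],
    d = if (length(x$d_per_iter)) x$d_per_iter[seq_len(n)] else NA_real_)
}

#' One-row summary of a reconstruction
#'
#' @param x a `pa_recon`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.pa_recon <- function(x, ...) {
  tibble::tibble(
    solver = x$solver,
    iters_run = x$iters_run,
    converged = x$converged,
    final_objective = if (length(x$objective_per_iter))
      x$objective_per_iter[x$iters_run] else NA_real_,
    final_d = if (length(x$d_per_iter))
      x$d_per_iter[length(x$d_per_iter)] else NA_real_,
    runtime_s = x$runtime_s)
}

#' @export
autoplot.pa_recon <- function(object, ...) {
  autoplot(object$image) +
    ggplot2::ggtitle(object$solver)
}
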