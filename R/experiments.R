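#' Experiment configurations
#'
#' An experiment regenerates one simulation-study table end to end: phantom
#' -> supersampled signal synthesis -> (optional noise) -> reconstruction
#' with each requested solver at each detector count -> metric table.
#' Configurations are plain lists, round-trippable through YAML; bundled
#' configs live under `system.file("extdata", "configs", package =
#' "patchtv")`.
#'
#' @param x a YAML file path or a list.
#' @return A validated `pa_experiment_config`.
#' @export
experiment_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    experiment = "unnamed",
    phantom = "shepp_logan",
    grid = list(nx = 128L),
    detector = list(line_length_mm = 76, distance_mm = 38,
                    orientation = "vertical"),
    time = list(fs_hz = 200e6, duration_s = 20e-6, t_offset_s = 0,
                c_mps = 1500),
    sampling_points = c(50L, 20L, 10L),
    solvers = c("patch_tv", "patch_re", "tv_gd"),
    params = list(),
    patch = list(),
    noise_snr_db = numeric(0),
    signal_supersample = 2L,
    seed = 1L)
  cfg <- modifyList(defaults, cfg)
  if (!is.character(cfg$phantom))
    stop("config field `phantom` must be a name or a YAML path")
  if (any(cfg$sampling_points <= 0))
    stop("config field `sampling_points` must be positive")
  known <- c("patch_tv", "patch_re", "tv_gd", "backprojection")
  bad <- setdiff(cfg$solvers, known)
  if (length(bad))
    stop("config field `solvers`: unknown solver(s) ", paste(bad, collapse = ", "))
  structure(cfg, class = "pa_experiment_config")
}

config_phantom <- function(cfg) {
  switch(cfg$phantom,
         shepp_logan = make_shepp_logan(),
         forbild = make_forbild(),
         phantom_from_yaml(cfg$phantom))
}

config_hash <- function(cfg) {
  # stable content hash without extra dependencies
  s <- paste(deparse(unclass(cfg)), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096)))
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2147483647
  sprintf("%08x", as.integer(h))
}

run_one_solver <- function(solver, g, proj, params, pcfg, reference) {
  switch(solver,
         patch_tv = patch_tv_reconstruct(g, proj, params, pcfg, reference),
         patch_re = patch_re_reconstruct(g, proj, params, pcfg, reference),
         tv_gd = tv_gd_reconstruct(g, proj, params, reference),
         backprojection = backproject(g, proj, reference))
}

#' Run a simulation-study experiment
#'
#' For every combination of detector count (and SNR, when noise levels are
#' configured) the phantom's signals are synthesised on a grid
#' `signal_supersample` times finer than the reconstruction raster, noise is
#' added, every configured solver is run, and PSNR / final distance are
#' recorded. Fully deterministic for a fixed config (the seed drives the
#' noise draws).
#'
#' @param cfg an [experiment_config()] (or YAML path / list).
#' @param keep_images keep the reconstructed `pa_recon` objects in the
#'   result (default `TRUE`; set `FALSE` to save memory in sweeps).
#' @param quiet suppress progress messages.
#' @return A `pa_experiment` with the metric tibble (`$metrics`), the
#'   reconstructions (`$recons`, named `solver/n_points/snr`), the ground
#'   truth (`$reference`) and the config and its hash.
#' @export
run_experiment <- function(cfg, keep_images = TRUE, quiet = FALSE) {
  cfg <- experiment_config(cfg)
  spec <- config_phantom(cfg)
  nx <- as.integer(cfg$grid$nx)
  reference <- rasterize(spec, nx, nx, supersample = 1L)
  det_cfg <- cfg$detector
  tg0 <- time_grid(cfg$time$fs_hz, cfg$time$duration_s, cfg$time$t_offset_s,
                   cfg$time$c_mps)
  params <- do.call(solver_params, cfg$params)
  pcfg <- do.call(patch_config, cfg$patch)
  snrs <- if (length(cfg$noise_snr_db)) cfg$noise_snr_db else Inf
  rows <- list()
  recons <- list()
  noise_idx <- 0L
  for (np in cfg$sampling_points) {
    det <- detector_line(np, det_cfg$line_length_mm, det_cfg$distance_mm,
                         det_cfg$orientation)
    tg <- suppressWarnings(ensure_time_coverage(tg0, det, spec$extent))
    proj <- build_projection_matrix(reference, det, tg)
    g0 <- simulate_signals(spec, det, tg, cfg$signal_supersample, nx)
    for (snr in snrs) {
      noise_idx <- noise_idx + 1L
      g <- if (is.finite(snr))
        add_noise(g0, snr, seed = cfg$seed + noise_idx) else g0
      for (solver in cfg$solvers) {
        if (!quiet)
          message(sprintf("[%s] %s, %d points, SNR %s dB",
                          cfg$experiment, solver, np, format(snr)))
        rec <- run_one_solver(solver, g, proj, params, pcfg, reference)
        key <- sprintf("%s/%d/%s", solver, np, format(snr))
        if (keep_images) recons[[key]] <- rec
        rows[[key]] <- tibble::tibble(
          experiment = cfg$experiment, solver = solver, n_points = np,
          snr_db = snr, psnr_db = psnr(rec$image, reference),
          d_final = distance_d(rec$image, reference),
          iters = rec$iters_run, runtime_s = rec$runtime_s)
      }
    }
  }
  structure(list(metrics = do.call(rbind, rows), recons = recons,
                 reference = reference, config = cfg,
                 config_hash = config_hash(cfg)),
            class = "pa_experiment")
}

#' @exportS3Method
print.pa_experiment <- function(x, ...) {
  cat(sprintf("<pa_experiment> %s (config %s)\n", x$config$experiment,
              x$config_hash))
  print(x$metrics)
  invisible(x)
}

#' Write an experiment's metric table as CSV
#'
#' @param exp a [run_experiment()] result.
#' @param path file path.
#' @export
write_metrics_csv <- function(exp, path) {
  stopifnot(inherits(exp, "pa_experiment"))
  m <- exp$metrics
  m$config_hash <- exp$config_hash
  write.table(m, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convergence line chart
#'
#' Distance-to-truth `d` against iteration, one line per solver, from the
#' reconstructions stored in an experiment (or a plain list of `pa_recon`
#' objects run with a `reference`).
#'
#' @param x a `pa_experiment` or list of `pa_recon` objects.
#' @param n_points restrict to one detector count (experiments only).
#' @return A ggplot object.
#' @export
plot_convergence <- function(x, n_points = NULL) {
  recs <- if (inherits(x, "pa_experiment")) {
    keep <- x$recons
    if (!is.null(n_points))
      keep <- keep[grepl(sprintf("/%d/", n_points), names(keep))]
    keep
  } else x
  if (!length(recs)) stop("no reconstructions to plot")
  recs <- Filter(function(r) length(r$d_per_iter) > 0, recs)
  if (!length(recs)) stop("no per-iteration distances recorded; run with a reference image")
  df <- do.call(rbind, lapply(recs, tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$d,
                                   colour = .data$solver)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "iteration", y = "distance d", colour = NULL)
}
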