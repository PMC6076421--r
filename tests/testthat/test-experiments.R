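test_that("experiment_config fills defaults and validates", {
  cfg <- experiment_config(list(experiment = "t"))
  expect_s3_class(cfg, "pa_experiment_config")
  expect_equal(cfg$grid$nx, 128L)
  expect_equal(cfg$sampling_points, c(50L, 20L, 10L))
  expect_equal(cfg$detector$distance_mm, 38)
  expect_error(experiment_config(list(sampling_points = c(10, -1))),
               "positive")
  expect_error(experiment_config(list(solvers = "magic")), "unknown solver")
  expect_error(experiment_config(list(phantom = 42)), "phantom")
})

test_that("bundled configs parse and carry the study parameters", {
  names <- c("shepp_perpendicular", "shepp_horizontal",
             "forbild_perpendicular", "forbild_noise", "smoke_32")
  for (nm in names) {
    path <- system.file("extdata", "configs", paste0(nm, ".yaml"),
                        package = "patchtv")
    expect_true(nzchar(path), info = nm)
    cfg <- experiment_config(path)
    expect_s3_class(cfg, "pa_experiment_config")
    expect_equal(cfg$experiment, nm)
  }
  noise <- experiment_config(system.file("extdata", "configs",
                                         "forbild_noise.yaml",
                                         package = "patchtv"))
  expect_equal(noise$noise_snr_db, c(10, 5, 0))
  expect_equal(noise$params$alpha, 0.73)
  horiz <- experiment_config(system.file("extdata", "configs",
                                         "shepp_horizontal.yaml",
                                         package = "patchtv"))
  expect_equal(horiz$detector$orientation, "horizontal")
})

test_that("config_hash is stable and sensitive", {
  c1 <- experiment_config(list(experiment = "a", seed = 1))
  c2 <- experiment_config(list(experiment = "a", seed = 1))
  c3 <- experiment_config(list(experiment = "a", seed = 2))
  expect_identical(patchtv:::config_hash(c1), patchtv:::config_hash(c2))
  expect_false(identical(patchtv:::config_hash(c1),
                         patchtv:::config_hash(c3)))
})

smoke_exp <- function() fx_cache("smoke_exp", function() {
  path <- system.file("extdata", "configs", "smoke_32.yaml",
                      package = "patchtv")
  suppressWarnings(run_experiment(experiment_config(path), quiet = TRUE))
})

test_that("the 32x32 smoke experiment runs the full grid quickly", {
  t0 <- proc.time()[["elapsed"]]
  exp <- smoke_exp()
  expect_lt(proc.time()[["elapsed"]] - t0, 60)
  m <- exp$metrics
  expect_equal(nrow(m), 4L)              # 4 solvers x 1 sampling
  expect_setequal(m$solver, c("patch_tv", "patch_re", "tv_gd",
                              "backprojection"))
  expect_true(all(is.finite(m$psnr_db)))
  expect_true(all(m$d_final > 0))
  # the paired-run ordering the smoke config is meant to show
  expect_gt(m$psnr_db[m$solver == "patch_tv"],
            m$psnr_db[m$solver == "tv_gd"])
})

test_that("experiments are deterministic and CSVs byte-identical", {
  exp1 <- smoke_exp()
  path <- system.file("extdata", "configs", "smoke_32.yaml",
                      package = "patchtv")
  exp2 <- suppressWarnings(run_experiment(experiment_config(path),
                                          quiet = TRUE))
  expect_equal(exp1$metrics$psnr_db, exp2$metrics$psnr_db, tolerance = 0)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  # runtime is machine noise, not part of the deterministic contract
  e1 <- exp1; e1$metrics$runtime_s <- 0
  e2 <- exp2; e2$metrics$runtime_s <- 0
  write_metrics_csv(e1, f1)
  write_metrics_csv(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noise seeds derive from the config seed", {
  cfg <- list(experiment = "n", phantom = "shepp_logan",
              grid = list(nx = 32L),
              time = list(fs_hz = 1e7, duration_s = 2e-5, t_offset_s = 0,
                          c_mps = 1500),
              sampling_points = 8L, solvers = "backprojection",
              noise_snr_db = c(10), signal_supersample = 2L, seed = 5L)
  e1 <- suppressWarnings(run_experiment(cfg, quiet = TRUE))
  e2 <- suppressWarnings(run_experiment(cfg, quiet = TRUE))
  cfg$seed <- 6L
  e3 <- suppressWarnings(run_experiment(cfg, quiet = TRUE))
  expect_identical(e1$metrics$psnr_db, e2$metrics$psnr_db)
  expect_false(identical(e1$metrics$psnr_db, e3$metrics$psnr_db))
})

test_that("plot_convergence draws one line per solver and rejects empties", {
  exp <- smoke_exp()
  pl <- plot_convergence(exp)
  expect_s3_class(pl, "ggplot")
  solvers_drawn <- unique(pl$data$solver)
  expect_setequal(solvers_drawn,
                  c("patch_tv", "patch_re", "tv_gd", "backprojection"))
  expect_error(plot_convergence(list()), "no reconstructions")
})

test_that("the command-line runner works end to end", {
  cli <- system.file("cli", "patv.R", package = "patchtv")
  expect_true(nzchar(cli))
  out <- tempfile("patvrun")
  cfg <- system.file("extdata", "configs", "smoke_32.yaml",
                     package = "patchtv")
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(cli, "run", cfg, "--out", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "iterations.csv")))
  expect_true(length(list.files(out, pattern = "\\.png$")) >= 1)
  status2 <- system2(rscript, c(cli, "plot", out),
                     stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "convergence.png")))
  unlink(out, recursive = TRUE)
})
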