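foam_config <- function(seed = 3, mean_d = 30, grid = 60,
                        border_policy = "exclude", closing = 10) {
  run_config(phantom = phantom_spec("packed_spheres", rep(grid, 3), 2,
                                    list(mean_diameter = mean_d,
                                         sd_diameter = 5,
                                         target_porosity = 0.4)),
             preprocess = list(closing_radius = closing),
             border_policy = border_policy,
             n_sections = 4, seed = seed)
}

test_that("volumes round-trip through multi-page TIFF stacks", {
  vol <- foam_volume(seed = 12, grid = 24)
  f <- tempfile(fileext = ".tif")
  write_volume_tiff(vol, f)
  back <- read_volume_tiff(f, voxel_size(vol), binarize = TRUE)
  expect_identical(unclass(back) > 0, unclass(vol) > 0)
  expect_equal(voxel_size(back), voxel_size(vol))
})

test_that("the sphere phantom closes the loop end to end", {
  cfg <- run_config(phantom = phantom_spec("single_sphere", c(48, 48, 48), 1,
                                           list(diameter = 30)),
                    n_sections = 3, seed = 1)
  rep <- run_analyze(cfg)
  med3d <- rep$summary$median[rep$summary$tag == "3D"]
  expect_close(med3d, 30, 2)
  expect_setequal(rep$summary$tag, c("3D", "MT", "MD", "BICD", "AECD", "SEM"))
  expect_true(all(rep$summary$n >= 1))
})

test_that("identical config and seed give a byte-identical report", {
  cfg <- foam_config()
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  run_analyze(cfg, out_dir = d1)
  run_analyze(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(file.exists(file.path(d1, "summary.csv")))
  expect_true(file.exists(file.path(d1, "regions.csv")))
})

test_that("reports read back from disk preserve the samples", {
  cfg <- foam_config(seed = 5)
  d <- file.path(tempdir(), "runC")
  rep <- run_analyze(cfg, out_dir = d)
  back <- read_report(d)
  expect_equal(back$samples[["MT"]], rep$samples[["MT"]], tolerance = 1e-12)
  expect_equal(back$config_hash, rep$config_hash)
})

test_that("the full segmentation path survives rendering degradations", {
  cfg <- run_config(phantom = phantom_spec("packed_spheres", c(48, 48, 48), 2,
                                           list(mean_diameter = 30,
                                                sd_diameter = 5,
                                                target_porosity = 0.4)),
                    render = list(blur_sigma = 1, noise_sd = 0.02,
                                  speckle_rate = 0.005),
                    preprocess = list(closing_radius = 10,
                                      min_solid_voxels = 3),
                    n_sections = 3, seed = 8)
  rep <- run_analyze(cfg)
  expect_setequal(rep$summary$tag, c("3D", "MT", "MD", "BICD", "AECD", "SEM"))
  expect_gt(rep$porosity, 0.2)
})

test_that("comparing a report with itself finds no differences", {
  rep <- run_analyze(foam_config(seed = 3))
  out <- run_compare(list(A = rep, B = rep))
  for (tag in names(out$comparisons)) {
    expect_false(any(out$comparisons[[tag]]$significant, na.rm = TRUE))
  }
  expect_equal(nrow(out$cv_table), 2 * 6)
})

test_that("small-pore and large-pore foams differ on every estimator", {
  repA <- run_analyze(foam_config(seed = 3, mean_d = 16, grid = 60,
                                  border_policy = "keep", closing = 8))
  repB <- run_analyze(foam_config(seed = 4, mean_d = 48, grid = 60,
                                  border_policy = "keep", closing = 16))
  out <- run_compare(list(small = repA, large = repB))
  for (tag in names(out$comparisons)) {
    expect_true(out$comparisons[[tag]]$significant["small", "large"],
                label = paste("tag", tag))
  }
})

test_that("invalid configurations fail with actionable messages", {
  expect_error(run_config(), "phantom spec or an input path")
  expect_error(run_config(input = "x.tif", preprocess = list(radius = 1)),
               "unknown preprocess keys")
  cfg <- run_config(input = "/nonexistent/input.tif")
  expect_error(run_analyze(cfg), "unreadable input")
})

test_that("configs round-trip through JSON files", {
  cfg <- foam_config(seed = 6)
  f <- tempfile(fileext = ".json")
  writeLines(poremetry:::config_json(cfg), f)
  cfg2 <- read_run_config(f)
  expect_equal(poremetry:::config_hash(cfg2), poremetry:::config_hash(cfg))
  bad <- tempfile(fileext = ".json")
  writeLines('{"voxel_size": 4.5, "frobnicate": 1}', bad)
  expect_error(read_run_config(bad), "invalid config keys")
})

test_that("the command-line wrapper drives the pipeline", {
  cli <- system.file("cli", "poremetry.R", package = "poremetry")
  expect_true(nzchar(cli))
  cfgfile <- tempfile(fileext = ".json")
  writeLines(poremetry:::config_json(foam_config(seed = 2, grid = 40)), cfgfile)
  outdir <- file.path(tempdir(), "cli_run")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "analyze", "--config", shQuote(cfgfile),
                   "--out", shQuote(outdir)),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(outdir, "report.json")))
  scored <- system2(file.path(R.home("bin"), "Rscript"),
                    c(cli, "score"), stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("\"3D\": 9", scored)))
})
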