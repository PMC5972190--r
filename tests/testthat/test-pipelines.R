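test_that("pipeline config serializes losslessly through YAML", {
  cfg <- pipeline_config(block_iterations = 2,
                         tophat_se = structuring_element("cross", 32),
                         binarize_threshold = 0.05)
  path <- file.path(tempdir(), "cfg.yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$block_iterations, 2)
  expect_equal(cfg2$tophat_se$shape, "cross")
  expect_equal(cfg2$tophat_se$radius, rep(32L, 3))
  expect_equal(cfg2$binarize_threshold, 0.05)
  expect_equal(cfg2$bilateral$mu, 0.00017)
  expect_error(read_config(file.path(tempdir(), "nope.yaml")), "not found")
  expect_error(pipeline_config(binarize_threshold = 1.5), "\\(0, 1\\)")
  expect_error(pipeline_config(block_iterations = -1), "non-negative")
})

test_that("the default configuration carries the reference protocol settings", {
  cfg <- pipeline_config()
  expect_equal(cfg$guided$r, 1)
  expect_equal(cfg$guided$eps, 1)
  expect_equal(cfg$bilateral$sigma, 1)
  expect_equal(cfg$bilateral$mu, 0.00017)
  expect_equal(cfg$tophat_se$shape, "cross")
  expect_equal(cfg$tophat_se$radius, rep(64L, 3))
  expect_equal(cfg$binarize_threshold, 0.035)
  expect_equal(cfg$geodesic_size, 15)
  expect_equal(cfg$closing_se$shape, "box")
  expect_equal(cfg$closing_se$radius, rep(2L, 3))
  expect_equal(cfg$dilation_se$shape, "cross")
  expect_equal(cfg$dilation_se$radius, rep(1L, 3))
  expect_equal(cfg$block_iterations, 4)   # 12 nonlinear filter applications
})

small_cfg <- function(...) {
  pipeline_config(tophat_se = structuring_element("cross", 16),
                  geodesic_size = 4, ...)
}

test_that("pipeline_2d on a constant volume returns it unchanged", {
  v <- intensity_volume(array(0.25, c(6, 8, 8)))
  run <- run_pipeline_2d(v, pipeline_config(block_iterations = 1))
  expect_s3_class(run, "otoct_run_2d")
  expect_equal(run$volume$data, v$data, tolerance = 1e-12)
})

test_that("block_iterations = 0 reduces the 2D chain to histogram + sharpen", {
  set.seed(60)
  v <- intensity_volume(array(runif(10 * 12 * 12), c(10, 12, 12)))
  run0 <- run_pipeline_2d(v, pipeline_config(block_iterations = 0))
  expect_equal(nrow(run0$report), 3)
  expect_equal(run0$report$stage, c("load", "histogram_match", "sharpen"))
  manual <- sharpen(histogram_match_slices(v))
  expect_identical(run0$volume$data, manual$data)
  run1 <- run_pipeline_2d(v, pipeline_config(block_iterations = 1))
  expect_equal(nrow(run1$report), 6)
})

test_that("histogram stage removes z-axis intensity drift", {
  set.seed(61)
  nz <- 24
  drift_amp <- 0.1
  x <- array(0.4 + rnorm(nz * 40 * 40, 0, 0.02), c(nz, 40, 40))
  drift <- drift_amp * ((seq_len(nz) - 1) / (nz - 1) - 0.5)
  x <- pmin(pmax(x + array(drift, c(nz, 40, 40)), 0), 1)
  pre_range <- diff(range(apply(x, 1, mean)))
  matched <- histogram_match_slices(intensity_volume(x))$data
  post_range <- diff(range(apply(matched, 1, mean)))
  expect_gte(pre_range, drift_amp * 0.9)
  expect_lt(post_range, 0.1 * pre_range)
})

test_that("pipeline_2d reduces noise on a flat block", {
  blk <- generate_flat_noise_block(c(32, 32, 32), 0.4, 0.05, seed = 62)
  run <- run_pipeline_2d(blk, pipeline_config(block_iterations = 1))
  core <- 9:24
  expect_lt(sd(run$volume$data[core, core, core]),
            0.5 * sd(blk$data[core, core, core]))
})

test_that("pipeline_3d artifacts obey the mask algebra", {
  ph <- generate_phantom(small_phantom_spec(seed = 63))
  run <- run_pipeline_3d(ph$volume, small_cfg())
  expect_s3_class(run, "otoct_run_3d")
  expect_equal(nrow(run$report), 8)
  expect_identical(run$segmented$data,
                   run$denoised$data * run$mask$data)
  # the final mask is a superset of the geodesic-opening output
  gmask <- geodesic_opening(binarize(run$denoised, 0.035), 4, 26)
  expect_true(all(run$mask$data >= gmask$data))
})

test_that("pipeline_3d on an all-zero-signal volume yields an empty mask", {
  v <- intensity_volume(array(0, c(40, 40, 40)))
  run <- run_pipeline_3d(v, small_cfg())
  expect_equal(sum(run$mask$data), 0)
  expect_equal(max(run$segmented$data), 0)
})

test_that("manual masks are intersected with the automatic mask", {
  ph <- generate_phantom(small_phantom_spec(seed = 64))
  cfg <- small_cfg()
  base <- run_pipeline_3d(ph$volume, cfg)
  ones <- binary_mask(array(TRUE, dim(ph$volume)))
  with_ones <- run_pipeline_3d(ph$volume, cfg, manual_mask = ones)
  expect_identical(with_ones$mask$data, base$mask$data)
  expect_equal(nrow(with_ones$report), 9)

  half <- array(FALSE, dim(ph$volume))
  half[1:32, , ] <- TRUE
  with_half <- run_pipeline_3d(ph$volume, cfg,
                               manual_mask = binary_mask(half))
  expect_identical(with_half$mask$data, base$mask$data & half)
  expect_error(run_pipeline_3d(ph$volume, cfg,
                               manual_mask = binary_mask(array(TRUE,
                                                               c(4, 4, 4)))),
               "dimension")
})

test_that("stage failures name the failing stage", {
  set.seed(66)
  x <- array(0.25, c(6, 8, 8))     # constant reference slice ...
  x[2, , ] <- runif(64)            # ... but a non-constant slice elsewhere
  expect_error(run_pipeline_2d(intensity_volume(x), pipeline_config(
    histogram = list(reference_slice = 1, n_quantiles = 256))),
    "histogram_match")
})

test_that("save_run round-trips outputs, config and report", {
  ph <- generate_phantom(small_phantom_spec(seed = 65))
  cfg <- small_cfg()
  run <- run_pipeline_3d(ph$volume, cfg)
  out <- file.path(tempdir(), "run3d")
  save_run(run, out)
  expect_true(all(file.exists(file.path(out, c("denoised.nrrd", "mask.nrrd",
                                               "segmented.nrrd",
                                               "config.yaml",
                                               "report.json")))))
  report <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(length(report), 8)
  expect_equal(vapply(report, `[[`, "", "stage")[1], "load")
  # rerun from the echoed config: identical mask voxel count
  cfg2 <- read_config(file.path(out, "config.yaml"))
  run2 <- run_pipeline_3d(ph$volume, cfg2)
  expect_identical(run2$mask$data, run$mask$data)
  mask_rt <- read_mask(file.path(out, "mask.nrrd"))
  expect_identical(mask_rt$data, run$mask$data)
  expect_error(save_run(run, "/no/such/parent/run"), "parent")
})
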