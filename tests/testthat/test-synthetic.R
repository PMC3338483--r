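test_that("truncated-Normal calibration reproduces target means exactly", {
  cases <- list(c(29.5, 11.3, 0), c(7.6, 3.1, 0), c(1340, 470, 0),
                c(1.6, 0.8, 1), c(2.2, 1.5, 1), c(10.4, 7.3, 2))
  for (cs in cases) {
    tn <- match_truncnorm(cs[1], cs[2], cs[3])
    m <- geledge:::.truncnorm_moments(tn$mu, tn$sigma, cs[3])
    expect_equal(unname(m["mean"]), cs[1], tolerance = 1e-6)
    # sd matches whenever attainable for this truncation bound
    expect_lte(tn$sd_attained, cs[2] * (1 + 1e-6))
  }
})

test_that("sampled populations reproduce configured pooled moments", {
  low <- preset_conditions("matrigel40_low")
  sh <- sample_cell_shapes(low, 1e4, seed = 42)
  expect_equal(mean(sh$area), 1340, tolerance = 0.02)
  expect_equal(mean(sh$aspect_ratio), 10.4, tolerance = 0.02)
  expect_equal(sd(sh$area), 470, tolerance = 0.05)
  expect_true(all(sh$area > 0))
  expect_true(all(sh$aspect_ratio >= 1))
  # two populations present at the interface
  expect_setequal(unique(sh$component), c("spindle", "rounded"))
})

test_that("sampling is deterministic under a fixed seed", {
  low <- preset_conditions("matrigel40_low")
  expect_identical(sample_cell_shapes(low, 50, seed = 7),
                   sample_cell_shapes(low, 50, seed = 7))
  tr1 <- simulate_tracks(preset_conditions("glass"), 5, seed = 9)
  tr2 <- simulate_tracks(preset_conditions("glass"), 5, seed = 9)
  expect_identical(tr1, tr2)
})

test_that("zero spindle fraction collapses to the single rounded population", {
  high <- preset_conditions("matrigel40_high")
  sh <- sample_cell_shapes(high, 1e4, seed = 3)
  expect_setequal(unique(sh$component), "rounded")
  expect_equal(mean(sh$aspect_ratio), 1.6, tolerance = 0.02)
})

test_that("an infeasible mixture is rejected with a clear error", {
  # pooled AR 10.4 +/- 7.3 cannot be split half-and-half against a rounded
  # component at 1.6: the implied spindle variance is negative
  bad <- condition_params("bad", 1340, 470, 10.4, 7.3, 29.5, 11.3,
                          spindle_fraction = 0.5)
  expect_error(sample_cell_shapes(bad, 10, seed = 1), "infeasible mixture")
})

test_that("depth profiles interpolate between interface and bulk", {
  pr <- depth_profile_params(1340, 400, 100)
  expect_equal(profile_value(pr, 0), 1340)
  expect_equal(profile_value(pr, 1e9), 400)
  expect_equal(profile_value(pr, 100 * log(2)), 870)
  cd <- condition_at_depth(preset_conditions("matrigel40_low"),
                           preset_conditions("matrigel40_high"), 100 * log(2))
  expect_equal(cd$area_mean, 870)
})

test_that("track path length equals speed times observation time exactly", {
  par <- condition_params("const", 500, 100, 1.5, 0.3, 30, 0)
  cfg <- imaging_config(image_shape = c(1024, 1024))
  tr <- simulate_tracks(par, 4, cfg, persistence = 0.7, seed = 5)
  for (i in unique(tr$cell_id)) {
    t1 <- tr[tr$cell_id == i, ]
    expect_equal(nrow(t1), 37)
    path <- sum(sqrt(diff(t1$x)^2 + diff(t1$y)^2))
    expect_equal(path, 360, tolerance = 1e-9)    # 30 um/hr x 12 h
    expect_equal(track_speed(t1, 20), 30, tolerance = 1e-9)
  }
})

test_that("drift is additive, recorded, and zero at zero scale", {
  par <- preset_conditions("glass")
  cfg <- imaging_config()
  tr <- simulate_tracks(par, 3, cfg, seed = 2, margin = 120)
  d0 <- apply_drift(tr, cfg, 0, seed = 4)
  expect_equal(d0$tracks$x, tr$x)
  expect_true(all(d0$drift$dx == 0))
  d1 <- apply_drift(tr, cfg, 1.5, seed = 4)
  idx <- match(d1$tracks$frame, d1$drift$frame)
  expect_equal(d1$tracks$x - d1$drift$dx[idx], tr$x, tolerance = 1e-12)
  expect_equal(d1$tracks$y - d1$drift$dy[idx], tr$y, tolerance = 1e-12)
  # per-frame drift step length is the configured scale
  step <- sqrt(diff(d1$drift$dx)^2 + diff(d1$drift$dy)^2)
  expect_equal(step, rep(1.5, 36), tolerance = 1e-9)
})

test_that("datasets round-trip through TIFF and CSV bit-exactly", {
  sh <- sample_cell_shapes(preset_conditions("matrigel40_high"), 5, seed = 8)
  cfg <- imaging_config(image_shape = c(128, 128))
  pl <- render_plane(sh, cfg, seed = 9)
  out <- withr::local_tempdir()
  write_dataset(list(pl$image), pl$truth, out, "demo",
                metadata = list(pixel_size = 1))
  back <- read_stack(file.path(out, "demo.tif"))
  expect_identical(back[[1]], pl$image)
  truth_back <- read.csv(file.path(out, "demo_truth.csv"))
  expect_equal(nrow(truth_back), nrow(pl$truth))
  # regeneration under the same seed writes byte-identical CSVs
  pl2 <- render_plane(sh, cfg, seed = 9)
  write_dataset(list(pl2$image), pl2$truth, out, "demo2")
  expect_identical(readBin(file.path(out, "demo_truth.csv"), "raw", 1e6),
                   readBin(file.path(out, "demo2_truth.csv"), "raw", 1e6))
})

test_that("an empty shape list renders pure background noise", {
  sh <- sample_cell_shapes(preset_conditions("matrigel40_high"), 1, seed = 1)[0, ]
  pl <- render_plane(sh, imaging_config(image_shape = c(64, 64)), seed = 2)
  expect_equal(nrow(pl$truth), 0)
  expect_lt(max(pl$image), 0.35)    # background + noise only
})
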