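test_that("a rasterized disk measures its analytic area and unit aspect ratio", {
  reg <- raster_ellipse_region(10, 10, noise = 0.03)
  expect_equal(measure_area(reg, 1), pi * 100, tolerance = 0.05)
  expect_equal(ellipse_aspect_ratio(reg), 1, tolerance = 0.02)
})

test_that("area scales with the square of the pixel size; AR does not", {
  reg <- raster_ellipse_region(12, 6)
  expect_equal(measure_area(reg, 0.5), measure_area(reg, 1) / 4)
  expect_equal(measure_area(reg, 1), reg$n_px)
  ar1 <- ellipse_aspect_ratio(reg)
  # AR uses pixel moments only, so it is pixel-size invariant by construction
  expect_equal(ar1, 2, tolerance = 0.05)
})

test_that("the moment ellipse recovers the drawn aspect ratio at any angle", {
  for (phi in c(0, 0.4, 1.1, 2.3)) {
    reg <- raster_ellipse_region(20, 5, phi = phi)
    expect_equal(ellipse_aspect_ratio(reg), 4, tolerance = 0.05)
  }
})

test_that("the aspect ratio is exactly invariant under rotation of a region", {
  reg <- raster_ellipse_region(20, 5, phi = 0.4)
  ar0 <- ellipse_aspect_ratio(reg)
  for (th in c(0.3, 1.2, 2.8)) {
    rot <- reg
    rot$px <- cbind(cos(th) * reg$px[, 1] - sin(th) * reg$px[, 2],
                    sin(th) * reg$px[, 1] + cos(th) * reg$px[, 2])
    expect_equal(ellipse_aspect_ratio(rot), ar0, tolerance = 1e-9)
  }
})

test_that("segmentation finds exactly the rendered cells", {
  cfg <- imaging_config(image_shape = c(96, 96), noise_sd = 0.03)
  expect_length(segment_plane(render_plane(
    sample_cell_shapes(preset_conditions("matrigel40_high"), 1, 1)[0, ],
    cfg, seed = 3)$image), 0)
  # areas well above the min_area floor so the generator count is recovered
  par <- condition_params("seg", 500, 80, 1.5, 0.3, 10, 2)
  sh <- sample_cell_shapes(par, 10, seed = 4)
  pl <- render_plane(sh, imaging_config(image_shape = c(512, 512)), seed = 5)
  regs <- segment_plane(pl$image)
  expect_length(regs, 10)
})

test_that("touching cells merge into a single region (no splitting)", {
  img <- matrix(0.1, 64, 64)
  img[geledge:::.ellipse_pixels(24, 32, 8, 8, 0, c(64, 64))] <- 0.8
  img[geledge:::.ellipse_pixels(38, 32, 8, 8, 0, c(64, 64))] <- 0.8
  regs <- segment_plane(img, min_area = 20)
  expect_length(regs, 1)
})

test_that("diagonally touching pixels belong to one 8-connected component", {
  img <- matrix(0.1, 32, 32)
  img[geledge:::.ellipse_pixels(12, 12, 4, 4, 0, c(32, 32))] <- 0.8
  img[geledge:::.ellipse_pixels(17, 17, 3, 3, 0, c(32, 32))] <- 0.8
  regs <- segment_plane(img, min_area = 5)
  expect_length(regs, 1)
})

test_that("height origin normalization shifts to the first populated plane", {
  rec <- tibble::tibble(cell_id = 1:3, plane_z = c(10, 10, 50), area = 1,
                        aspect_ratio = 1)
  out <- normalize_height_origin(rec)
  expect_equal(sort(unique(out$plane_z)), c(0, 40))
  expect_identical(normalize_height_origin(out), out)   # idempotent
  expect_error(normalize_height_origin(rec[0, ]), "no cells")
})

test_that("height profiles summarize bins with sample sd and flag singletons", {
  rec <- tibble::tibble(plane_z = c(10, 20, 80), area = c(2, 4, 6))
  pr <- profile_by_height(rec, bin_edges = c(0, 50, 100), metric = "area")
  expect_equal(pr$mean, c(3, 6))
  expect_equal(pr$n, c(2, 1))
  expect_equal(pr$sd, c(sd(c(2, 4)), 0))
  expect_true(pr$low_n[2])
})

test_that("exponential profile fit recovers noiseless parameters within 1%", {
  z <- c(0, 25, 60, 120, 250, 600)
  pr <- tibble::tibble(z = z, mean = 400 + (1340 - 400) * exp(-z / 100))
  fit <- fit_exponential_profile(pr)
  expect_false(fit$degenerate)
  expect_equal(fit$m0, 1340, tolerance = 0.01)
  expect_equal(fit$m_bulk, 400, tolerance = 0.01)
  expect_equal(fit$lambda, 100, tolerance = 0.01)
})

test_that("flat profiles are flagged degenerate with the mean as bulk value", {
  pr <- tibble::tibble(z = c(0, 50, 100, 200), mean = rep(5, 4))
  fit <- fit_exponential_profile(pr)
  expect_true(fit$degenerate)
  expect_equal(fit$m_bulk, 5)
})

test_that("fitted decay lengths rank-order generated decay lengths", {
  z <- c(0, 30, 80, 150, 300, 600)
  fit_l <- function(lambda) {
    pr <- tibble::tibble(z = z, mean = 400 + 940 * exp(-z / lambda))
    fit_exponential_profile(pr)$lambda
  }
  expect_lt(fit_l(50), fit_l(150))
})

test_that("measured pooled morphometry matches generator truth", {
  # round-trip: generated -> rendered -> segmented -> measured
  sh <- sample_cell_shapes(preset_conditions("matrigel40_high"), 18, seed = 21)
  cfg <- imaging_config(image_shape = c(768, 768))
  pl <- render_plane(sh, cfg, seed = 22)
  m <- measure_plane(pl$image, 0)
  expect_equal(nrow(m), 18)
  # per-cell recovery within 5% for cells >= 100 px (match by centroid)
  big <- pl$truth[pl$truth$n_px >= 100, ]
  for (i in seq_len(nrow(big))) {
    j <- which.min((m$x - big$x[i])^2 + (m$y - big$y[i])^2)
    expect_equal(m$area[j], big$area[i], tolerance = 0.05)
    expect_equal(m$aspect_ratio[j], big$aspect_ratio[i], tolerance = 0.05)
  }
  expect_equal(mean(m$area), mean(pl$truth$area), tolerance = 0.02)
})

test_that("interface planes show larger cells than bulk planes", {
  low <- preset_conditions("matrigel40_low")
  high <- preset_conditions("matrigel40_high")
  cfg <- imaging_config(image_shape = c(768, 768))
  m_low <- measure_condition_planes(low, 12, 31, 32, config = cfg)
  m_high <- measure_condition_planes(high, 12, 33, 34, config = cfg)
  rec <- rbind(tibble::tibble(plane_z = 0, area = m_low$area),
               tibble::tibble(plane_z = 600, area = m_high$area))
  pr <- profile_by_height(rec, metric = "area")
  expect_gt(pr$mean[1], pr$mean[nrow(pr)])
})
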