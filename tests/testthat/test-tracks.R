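test_that("identical frames register with zero offsets", {
  set.seed(1)
  f <- matrix(runif(64 * 64), 64, 64)
  reg <- register_frames(list(f, f, f))
  expect_equal(max(abs(as.matrix(reg$offsets[, c("dx_px", "dy_px")]))), 0,
               tolerance = 1e-9)
})

test_that("an integer content shift is recovered exactly (negated) as the offset", {
  set.seed(2)
  f <- matrix(runif(128 * 128), 128, 128)
  shifted <- geledge:::.roll_image(f, 5, -3)   # content moves +5 x, -3 y
  reg <- register_frames(list(f, shifted))
  expect_equal(reg$offsets$dx_px[2], -5, tolerance = 0.01)
  expect_equal(reg$offsets$dy_px[2], 3, tolerance = 0.01)
  # applying the offset re-aligns the frame with the reference
  realigned <- reg$corrected[[2]]
  core <- 20:100
  expect_equal(realigned[core, core], f[core, core])
})

test_that("featureless frames fall back to zero offset with a warning", {
  f <- matrix(0.5, 32, 32)
  expect_warning(reg <- register_frames(list(f, f)), "featureless")
  expect_equal(reg$offsets$dx_px[2], 0)
})

test_that("synthetic gel drift is recovered within 0.5 px RMS", {
  sc <- small_scene(drift_scale = 1.2)
  reg <- register_frames(sc$frames)
  err <- sqrt(mean((reg$offsets$dx_px + sc$drift$dx)^2 +
                   (reg$offsets$dy_px + sc$drift$dy)^2))
  expect_lt(err, 0.5)
})

test_that("a stationary detection yields one full-length track", {
  dets <- tibble::tibble(frame = 1:10, x = 50, y = 60)
  tr <- link_detections(dets, max_step = 5)
  expect_equal(unique(tr$cell_id), 1)
  expect_equal(nrow(tr), 10)
})

test_that("well-separated cells link without identity switches", {
  sc <- small_scene(n_cells = 4, speed_mean = 4, drift_scale = 0)
  dets <- dplyr::bind_rows(lapply(seq_along(sc$frames), function(k) {
    m <- measure_plane(sc$frames[[k]], 0, threshold = 0.65)
    tibble::tibble(frame = k, x = m$x, y = m$y)
  }))
  max_step <- 3 * 4 * 20 / 60
  # precondition of the linking-fidelity property: cells stay separated by
  # more than 4 x the per-frame step budget
  sep <- vapply(unique(sc$truth$frame), function(k) {
    tt <- sc$truth[sc$truth$frame == k, ]
    min(dist(cbind(tt$x, tt$y)))
  }, numeric(1))
  expect_gt(min(sep), 4 * max_step)
  tr <- link_detections(dets, max_step = max_step)
  expect_equal(length(unique(tr$cell_id)), 4)
  expect_equal(nrow(tr), 4 * length(sc$frames))
  # every linked track stays near exactly one truth track throughout
  for (i in unique(tr$cell_id)) {
    t1 <- tr[tr$cell_id == i, ]
    d_truth <- vapply(unique(sc$truth$cell_id), function(j) {
      tj <- sc$truth[sc$truth$cell_id == j, ]
      max(sqrt((t1$x - tj$x[t1$frame])^2 + (t1$y - tj$y[t1$frame])^2))
    }, numeric(1))
    expect_lt(min(d_truth), 1)   # one truth track matches every frame
  }
})

test_that("a detection gap splits the track instead of closing it", {
  dets <- tibble::tibble(frame = c(1:4, 6:10), x = 50, y = 60)
  tr <- link_detections(dets, max_step = 5, min_frac = 0.3)
  expect_equal(length(unique(tr$cell_id)), 2)
})

test_that("track speed is path length over observation time", {
  still <- tibble::tibble(x = rep(1, 5), y = rep(2, 5))
  expect_equal(track_speed(still, 20), 0)
  straight <- tibble::tibble(x = c(0, 10, 20, 30), y = 0)
  expect_equal(track_speed(straight, 20), 30)
  zigzag <- tibble::tibble(x = c(0, 10, 0, 10), y = 0)
  expect_equal(track_speed(zigzag, 20), 30)   # path, not displacement
  expect_error(track_speed(still[1, ], 20), "fewer than 2")
})

test_that("speed summaries report descriptive stats and a low-n warning", {
  tracks <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(cell_id = i, frame = 1:4,
                   x = seq(0, 3) * c(10, 20, 30)[i] / 3, y = 0)
  }))
  expect_warning(sm <- summarize_speeds(tracks, 20, "demo"), "15")
  expect_equal(sm$summary$mean, 20)
  expect_equal(sm$summary$sd, 10)
  expect_equal(sm$summary$n, 3)
})

test_that("unregistered drifted data overestimate speeds; registered do not", {
  sc <- small_scene(n_cells = 5, speed_mean = 8, drift_scale = 1.5)
  reg <- register_frames(sc$frames)
  dets <- dplyr::bind_rows(lapply(seq_along(sc$frames), function(k) {
    m <- measure_plane(sc$frames[[k]], 0, threshold = 0.65)
    tibble::tibble(frame = k, x = m$x, y = m$y)
  }))
  raw <- link_detections(dets, max_step = 3 * 8 * 20 / 60 + 2 * 1.5)
  sm_raw <- suppressWarnings(summarize_speeds(raw, 20))
  cor <- dets
  cor$x <- cor$x + reg$offsets$dx_px[cor$frame]
  cor$y <- cor$y + reg$offsets$dy_px[cor$frame]
  sm_cor <- suppressWarnings(summarize_speeds(
    link_detections(cor, max_step = 3 * 8 * 20 / 60), 20))
  truth_mean <- mean(unique(sc$truth[, c("cell_id", "true_speed")])$true_speed)
  expect_gt(sm_raw$summary$mean, truth_mean)          # drift inflates speed
  expect_equal(sm_cor$summary$mean, truth_mean, tolerance = 0.05)
})
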