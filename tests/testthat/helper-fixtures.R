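# Shared fixtures: keep FEM meshes small and image scenes compact so the
# suite stays fast; accuracy-critical checks build their own finer meshes.

small_mesh <- function(height = 20, radius = 100, fine = 2) {
  build_axisym_mesh(gel_geometry(height, radius), refine_radius = 8,
                    coarse_size = 10, fine_size = fine)
}

# draw a single rotated ellipse (semi-axes in px) in a blank noisy image and
# return the first segmented region
raster_ellipse_region <- function(a, b, phi = 0, size = 4 * ceiling(max(a, b)) + 9,
                                  noise = 0, seed = 1) {
  set.seed(seed)
  img <- matrix(0.1, size, size)
  # generic subpixel placement, as the renderer produces
  px <- geledge:::.ellipse_pixels((size + 1) / 2 + 0.3, (size + 1) / 2 + 0.3,
                                  a, b, phi, c(size, size))
  img[px] <- 0.8
  if (noise > 0) img <- img + matrix(rnorm(size^2, 0, noise), size, size)
  regs <- segment_plane(img, pixel_size = 1, min_area = 5)
  expect_length(regs, 1)
  regs[[1]]
}

# small, fast time-lapse scene for registration / linking tests
small_scene <- function(n_cells = 6, speed_mean = 20, drift_scale = 1,
                        seed = 11, n_speckles = 120) {
  params <- condition_params("test", 500, 100, 1.5, 0.3,
                             speed_mean, speed_mean / 4)
  cfg <- imaging_config(image_shape = c(256, 256), duration = 4)
  truth <- simulate_tracks(params, n_cells, cfg, persistence = 0.5,
                           seed = seed, margin = 60)
  dr <- apply_drift(truth, cfg, drift_scale, seed + 1)
  frames <- render_track_frames(dr$tracks, cfg, drift = dr$drift,
                                n_speckles = n_speckles, seed = seed + 2)
  list(params = params, config = cfg, truth = truth, drifted = dr$tracks,
       drift = dr$drift, frames = frames)
}

# enumeration oracle: exact two-sided rank-sum p-value by enumerating every
# assignment of the pooled values to the two groups (midranks for ties),
# using the same two-sided rule as the exact Mann-Whitney distribution
enum_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  p
}

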