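# Ground-truth migration tracks: persistent random walks with exact
# path-length speed, plus the global smooth gel drift (swelling) that the
# registration stage must remove.

#' Simulate ground-truth migration tracks
#'
#' Each cell draws a target speed from the condition's (truncated-Normal
#' calibrated) speed distribution; every frame it takes a step of exactly
#' `speed * frame_interval`, so the realized path-length speed equals the
#' target by construction. Step direction follows a persistent random walk
#' (wrapped-Normal turning angles with `E[cos(turn)] = persistence`;
#' `persistence = 0` gives i.i.d. uniform directions). Cells start on a
#' jittered grid inside the field and turn away from the field margin so no
#' track ever leaves the imaged region.
#'
#' @param params A [condition_params()] providing the speed distribution.
#' @param n_cells Number of cells (>= 1).
#' @param config An [imaging_config()]; field size is
#'   `image_shape * pixel_size` um.
#' @param persistence Direction correlation in `[0, 1)`. Interface cells
#'   migrate in a directed, mesenchymal fashion (default 0.7 there); bulk
#'   cells extend and retract processes with little net direction (0.2).
#' @param seed Integer seed.
#' @param margin Width (um) of the boundary band tracks must stay out of
#'   (leave room for the cell body and the applied drift).
#' @return A `track_truth` tibble: `cell_id`, `frame` (1-based), `t_hr`,
#'   `x`, `y` (um), `true_speed` (um/hr).
#' @export
simulate_tracks <- function(params, n_cells, config = imaging_config(),
                            persistence = 0.7, seed = 1, margin = 100) {
  stopifnot(inherits(params, "condition_params"), n_cells >= 1,
            persistence >= 0, persistence < 1)
  nf <- n_frames(config)
  field <- config$image_shape * config$pixel_size
  lo <- c(margin, margin)
  hi <- field - margin
  if (any(hi <= lo)) stop("margin too large for the field")
  dt_hr <- config$frame_interval / 60

  tn <- match_truncnorm(params$speed_mean, params$speed_sd, 0)
  set.seed(seed)
  speeds <- rtrunc(n_cells, tn)
  step_len <- speeds * dt_hr

  # jittered grid starting positions
  ngx <- ceiling(sqrt(n_cells * (hi[1] - lo[1]) / (hi[2] - lo[2])))
  ngy <- ceiling(n_cells / ngx)
  gx <- seq(lo[1], hi[1], length.out = ngx + 2)[-c(1, ngx + 2)]
  gy <- seq(lo[2], hi[2], length.out = ngy + 2)[-c(1, ngy + 2)]
  grid <- expand.grid(x = gx, y = gy)[seq_len(n_cells), ]
  jit <- pmin(diff(range(gx)) / max(1, ngx - 1), diff(range(gy)) / max(1, ngy - 1)) / 5
  start <- cbind(grid$x, grid$y) + matrix(runif(2 * n_cells, -jit, jit), ncol = 2)
  start <- cbind(pmin(pmax(start[, 1], lo[1]), hi[1]),
                 pmin(pmax(start[, 2], lo[2]), hi[2]))

  sd_turn <- if (persistence > 0) sqrt(-2 * log(persistence)) else Inf
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    pos <- matrix(NA_real_, nf, 2)
    pos[1, ] <- start[i, ]
    theta <- runif(1, 0, 2 * pi)
    for (k in seq_len(nf - 1)) {
      theta <- if (is.finite(sd_turn)) theta + rnorm(1, 0, sd_turn) else
        runif(1, 0, 2 * pi)
      prop <- pos[k, ] + step_len[i] * c(cos(theta), sin(theta))
      tries <- 0
      while ((prop[1] < lo[1] || prop[1] > hi[1] ||
              prop[2] < lo[2] || prop[2] > hi[2]) && tries < 200) {
        theta <- runif(1, 0, 2 * pi)   # turn away from the margin
        prop <- pos[k, ] + step_len[i] * c(cos(theta), sin(theta))
        tries <- tries + 1
      }
      pos[k + 1, ] <- prop
    }
    out[[i]] <- tibble::tibble(cell_id = i, frame = seq_len(nf),
                               t_hr = (seq_len(nf) - 1) * dt_hr,
                               x = pos[, 1], y = pos[, 2],
                               true_speed = speeds[i])
  }
  dplyr::bind_rows(out)
}

#' Apply a smooth global drift to tracks
#'
#' Emulates the gel swelling observed during long time-lapse acquisitions: a
#' single smooth offset sequence (per-frame steps of length `drift_scale`
#' whose direction wanders slowly) is added to every cell in the field. The
#' drift truth is returned for registration tests.
#'
#' @param tracks A [simulate_tracks()] tibble.
#' @param config The [imaging_config()] used for the tracks.
#' @param drift_scale Drift step length (um/frame), >= 0.
#' @param seed Integer seed.
#' @return A list: `tracks` (drifted positions), `drift` (tibble `frame`,
#'   `dx`, `dy` cumulative offsets in um; frame 1 is (0, 0)).
#' @export
apply_drift <- function(tracks, config, drift_scale = 1.5, seed = 1) {
  stopifnot(drift_scale >= 0)
  nf <- max(tracks$frame)
  set.seed(seed)
  theta0 <- runif(1, 0, 2 * pi)
  theta <- theta0 + cumsum(c(0, rnorm(nf - 2, 0, 0.25)))
  steps <- drift_scale * cbind(cos(theta), sin(theta))
  drift <- tibble::tibble(frame = seq_len(nf),
                          dx = c(0, cumsum(steps[, 1])),
                          dy = c(0, cumsum(steps[, 2])))
  idx <- match(tracks$frame, drift$frame)
  drifted <- tracks
  drifted$x <- tracks$x + drift$dx[idx]
  drifted$y <- tracks$y + drift$dy[idx]
  list(tracks = drifted, drift = drift)
}
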