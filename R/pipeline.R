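# End-to-end orchestration: config handling, the FEM height sweep, the
# synthetic generate -> measure -> compare experiment, and a plain-text
# reproduction report. A single run seed is expanded into independent
# per-stage child seeds so any stage can be replayed on its own.

#' Default run configuration
#'
#' @param seed Global run seed (expanded into per-stage child seeds).
#' @param heights FEM sweep heights (um).
#' @param n_tracks Tracks per condition for the migration experiment.
#' @param n_cells_morpho Cells per condition for the morphology experiment.
#' @param drift_scale Gel drift (um/frame) applied to time-lapse data.
#' @param conditions Named list of [condition_params()]; defaults to the
#'   three built-in presets.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, heights = c(12.5, 25, 50, 100, 200),
                               n_tracks = 45, n_cells_morpho = 36,
                               drift_scale = 1.5,
                               conditions = preset_conditions()) {
  structure(list(seed = as.integer(seed), heights = heights,
                 n_tracks = n_tracks, n_cells_morpho = n_cells_morpho,
                 drift_scale = drift_scale, conditions = conditions,
                 material = elastic_material(), indenter = indenter_spec()),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat schema: `seed`, `heights`, `n_tracks`, `n_cells_morpho`,
#' `drift_scale`, `material: {youngs_modulus, poisson_ratio}`,
#' `indenter: {radius, max_depth, n_steps}`, and `conditions:` a named map of
#' condition entries (`area_mean`, `area_sd`, `ar_mean`, `ar_sd`,
#' `speed_mean`, `speed_sd`, `spindle_fraction`). Missing keys fall back to
#' the defaults. A committed example lives at
#' `system.file("extdata", "example-config.yaml", package = "geledge")`.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in c("seed", "heights", "n_tracks", "n_cells_morpho", "drift_scale")) {
    if (!is.null(y[[k]])) cfg[[k]] <- as.numeric(unlist(y[[k]]))
  }
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(y$material)) {
    cfg$material <- elastic_material(
      y$material$youngs_modulus %||% 450,
      y$material$poisson_ratio %||% 0.45)
  }
  if (!is.null(y$indenter)) {
    cfg$indenter <- indenter_spec(y$indenter$radius %||% 5,
                                  y$indenter$max_depth %||% 5,
                                  y$indenter$n_steps %||% 10)
  }
  if (!is.null(y$conditions)) {
    cfg$conditions <- lapply(names(y$conditions), function(nm) {
      c0 <- y$conditions[[nm]]
      condition_params(nm, c0$area_mean, c0$area_sd, c0$ar_mean, c0$ar_sd,
                       c0$speed_mean, c0$speed_sd,
                       c0$spindle_fraction %||% 0)
    })
    names(cfg$conditions) <- names(y$conditions)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expand the run seed into named child seeds (< 2^31), one per stage
child_seeds <- function(seed, stages) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' Run the FEM height sweep and write its outputs
#'
#' @param config A [default_run_config()] (or [read_run_config()]) list.
#' @param out_dir Output directory.
#' @param write_fields Also write per-height VTK stress fields and
#'   force-deflection CSVs (slower; re-solves each height).
#' @return The sweep tibble, invisibly; writes `fem_sweep.csv`.
#' @export
run_fem_sweep <- function(config, out_dir, write_fields = FALSE) {
  if (length(config$heights) == 0) stop("config has an empty heights list")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[3]
  sweep <- height_sweep(config$heights, config$material, config$indenter)
  message(sprintf("FEM sweep over %d heights: %.1f s, %s elements",
                  nrow(sweep), proc.time()[3] - t0,
                  paste(sweep$n_elements, collapse = "/")))
  write.csv(sweep, file.path(out_dir, "fem_sweep.csv"), row.names = FALSE)
  if (write_fields) {
    for (h in config$heights) {
      mesh <- build_axisym_mesh(gel_geometry(h))
      res <- solve_contact_indentation(mesh, config$material, config$indenter)
      write_vtk_field(res, file.path(out_dir, sprintf("field_h%g.vtk", h)))
      write.csv(res$steps,
                file.path(out_dir, sprintf("force_deflection_h%g.csv", h)),
                row.names = FALSE)
    }
  }
  invisible(sweep)
}

#' Run the full synthetic experiment
#'
#' For each configured condition: sample cell shapes and render morphology
#' planes, segment and measure them; simulate tracks, apply gel drift, render
#' the time-lapse, register, detect, link and summarize speeds. Finally
#' compares the interface (low) against the bulk (high) condition with the
#' study's tests. All stages derive independent child seeds from the run
#' seed.
#'
#' @param config A [default_run_config()] list.
#' @param out_dir Output directory for CSVs.
#' @param low,high Names (in `config$conditions`) of the interface and bulk
#'   conditions compared in the final stats table.
#' @return Invisibly, a list: `morphometry` (per-cell tibble), `speeds`
#'   (per-cell tibble), `stats` (comparison tibble).
#' @export
run_synthetic_experiment <- function(config, out_dir,
                                     low = "matrigel40_low",
                                     high = "matrigel40_high") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- child_seeds(config$seed,
                       c("shapes", "render", "tracks", "drift", "movie"))
  morpho <- list()
  speeds <- list()
  for (nm in names(config$conditions)) {
    par <- config$conditions[[nm]]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop("condition '", nm, "', stage ", what, " (seed ", config$seed,
             "): ", conditionMessage(e), call. = FALSE)
      })
    }
    morpho[[nm]] <- stage("morphometry",
      measure_condition_planes(par, config$n_cells_morpho,
                               seed_shapes = seeds["shapes"] + match(nm, names(config$conditions)),
                               seed_render = seeds["render"] + match(nm, names(config$conditions))))
    sp <- stage("tracking",
      recover_condition_speeds(par, config$n_tracks,
        persistence = if (grepl("high", nm)) 0.2 else 0.7,
        drift_scale = config$drift_scale,
        seed_tracks = seeds["tracks"] + match(nm, names(config$conditions)),
        seed_drift = seeds["drift"] + match(nm, names(config$conditions)),
        seed_movie = seeds["movie"] + match(nm, names(config$conditions))))
    speeds[[nm]] <- tibble::tibble(condition = nm, sp$speeds)
  }
  morpho_tbl <- dplyr::bind_rows(lapply(names(morpho), function(nm) {
    tibble::tibble(condition = nm, morpho[[nm]])
  }))
  speeds_tbl <- dplyr::bind_rows(speeds)

  stats_tbl <- NULL
  if (all(c(low, high) %in% names(config$conditions))) {
    s_lo <- speeds_tbl$speed[speeds_tbl$condition == low]
    s_hi <- speeds_tbl$speed[speeds_tbl$condition == high]
    a_lo <- morpho_tbl$area[morpho_tbl$condition == low]
    a_hi <- morpho_tbl$area[morpho_tbl$condition == high]
    if (min(length(s_lo), length(s_hi), length(a_lo), length(a_hi)) < 2) {
      warning("fewer than 2 observations per group; skipping tests")
    } else {
      stats_tbl <- dplyr::bind_rows(
        students_t(s_lo, s_hi, labels = paste0(c(low, high), " speed")),
        wilcoxon_rank_sum(s_lo, s_hi, labels = paste0(c(low, high), " speed")),
        students_t(a_lo, a_hi, labels = paste0(c(low, high), " area")),
        wilcoxon_rank_sum(a_lo, a_hi, labels = paste0(c(low, high), " area")),
        one_way_anova(list(s_lo, s_hi), labels = paste0(c(low, high), " speed"))
      )
    }
  }
  write.csv(morpho_tbl, file.path(out_dir, "morphometry.csv"), row.names = FALSE)
  write.csv(speeds_tbl, file.path(out_dir, "speeds.csv"), row.names = FALSE)
  if (!is.null(stats_tbl)) {
    write.csv(stats_tbl, file.path(out_dir, "stats.csv"), row.names = FALSE)
  }
  invisible(list(morphometry = morpho_tbl, speeds = speeds_tbl,
                 stats = stats_tbl))
}

#' Render, segment and measure the morphology planes of one condition
#'
#' Splits the requested cells over several rendered fields (large spindle
#' cells do not pack densely), measures every field, and pools the per-cell
#' records.
#'
#' @param params A [condition_params()].
#' @param n_cells Total cells to render and measure.
#' @param seed_shapes,seed_render Stage seeds.
#' @param cells_per_field Cells rendered per field.
#' @param config An [imaging_config()].
#' @return Per-cell tibble (`cell_id`, `area`, `aspect_ratio`, ...) pooled
#'   over fields.
#' @export
measure_condition_planes <- function(params, n_cells, seed_shapes = 1,
                                     seed_render = 2, cells_per_field = 9,
                                     config = imaging_config(image_shape = c(768, 768))) {
  shapes <- sample_cell_shapes(params, n_cells, seed = seed_shapes)
  n_fields <- ceiling(n_cells / cells_per_field)
  recs <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    rows <- ((f - 1) * cells_per_field + 1):min(f * cells_per_field, n_cells)
    pl <- render_plane(shapes[rows, ], config, seed = seed_render + f)
    m <- measure_plane(pl$image, plane_z = 0, pixel_size = config$pixel_size)
    m$field <- f
    recs[[f]] <- m
  }
  out <- dplyr::bind_rows(recs)
  out$cell_id <- seq_len(nrow(out))
  out
}

#' Generate, drift, image, register and track one condition's movie
#'
#' The end-to-end migration recovery used by the experiment runner and the
#' acceptance analysis: simulate ground-truth tracks, add gel drift, render
#' the time-lapse, estimate and apply registration offsets to per-frame
#' detections, link them into tracks and summarize path-length speeds.
#'
#' The end-to-end recovery mirrors the study design: the cells are split over
#' `replicates` independently imaged fields (hydrogels), each with its own
#' gel drift, and the per-cell speeds are pooled.
#'
#' @param params A [condition_params()].
#' @param n_tracks Total number of cells across all replicates.
#' @param persistence Direction persistence of the walks.
#' @param drift_scale Gel drift (um/frame).
#' @param seed_tracks,seed_drift,seed_movie Stage seeds.
#' @param replicates Number of independently imaged fields (default 3, the
#'   study's N = 3 hydrogels per condition).
#' @param det_threshold Intensity threshold for movie detections. The cell
#'   label renders at 0.8 while gel-debris speckles stay below ~0.55, so a
#'   fixed 0.65 cut isolates cells; adaptive (Otsu) thresholds are unreliable
#'   when only a few cells occupy the frame.
#' @param config An [imaging_config()].
#' @return A list: `summary`, `speeds` (pooled per-cell tibble), `truth`
#'   (tibble of per-cell true speeds), `offsets` and `drift` of the first
#'   replicate, `n_lost` (cells whose tracks were dropped).
#' @export
recover_condition_speeds <- function(params, n_tracks, persistence = 0.7,
                                     drift_scale = 1.5, seed_tracks = 1,
                                     seed_drift = 2, seed_movie = 3,
                                     replicates = 3, det_threshold = 0.65,
                                     config = imaging_config(image_shape = c(1024, 1024))) {
  per_rep <- rep(n_tracks %/% replicates, replicates)
  if (n_tracks %% replicates) {
    per_rep[seq_len(n_tracks %% replicates)] <- per_rep[1] + 1L
  }
  speeds <- list()
  truth_speeds <- list()
  first <- NULL
  for (r in seq_len(replicates)) {
    truth <- simulate_tracks(params, per_rep[r], config, persistence,
                             seed_tracks + 97L * r)
    dr <- apply_drift(truth, config, drift_scale, seed_drift + 97L * r)
    frames <- render_track_frames(dr$tracks, config, drift = dr$drift,
                                  seed = seed_movie + 97L * r)
    reg <- register_frames(frames)
    dets <- dplyr::bind_rows(lapply(seq_along(frames), function(k) {
      m <- measure_plane(frames[[k]], plane_z = 0,
                         pixel_size = config$pixel_size, min_area = 50,
                         threshold = det_threshold)
      if (nrow(m)) tibble::tibble(frame = k, x = m$x, y = m$y)
    }))
    # offsets are corrections: adding them removes the drift from detections
    dets$x <- dets$x + reg$offsets$dx_px[dets$frame] * config$pixel_size
    dets$y <- dets$y + reg$offsets$dy_px[dets$frame] * config$pixel_size
    max_step <- 3 * params$speed_mean * config$frame_interval / 60
    tracks <- link_detections(dets, max_step = max_step)
    sm <- suppressWarnings(
      summarize_speeds(tracks, config$frame_interval, params$label))
    sm$speeds$replicate <- r
    speeds[[r]] <- sm$speeds
    truth_speeds[[r]] <- tibble::tibble(replicate = r,
                                        unique(truth[, c("cell_id", "true_speed")]))
    if (r == 1) first <- list(offsets = reg$offsets, drift = dr$drift)
  }
  speeds <- dplyr::bind_rows(speeds)
  speeds$cell_id <- seq_len(nrow(speeds))
  list(summary = tibble::tibble(group = params$label, n = nrow(speeds),
                                mean = mean(speeds$speed),
                                sd = sd(speeds$speed)),
       speeds = speeds,
       truth = dplyr::bind_rows(truth_speeds),
       offsets = first$offsets, drift = first$drift,
       n_lost = n_tracks - nrow(speeds))
}

#' Write a human-readable reproduction report
#'
#' Tabulates the quantities recovered by a completed run (`fem_sweep.csv`,
#' `speeds.csv`, `morphometry.csv`, `stats.csv` in `out_dir`) against the
#' study's reference values and writes `report.txt`. Regeneration from the
#' same directory is idempotent.
#'
#' @param out_dir Directory holding the run outputs.
#' @return The report lines, invisibly; writes `report.txt`.
#' @export
reproduce_report <- function(out_dir) {
  need <- c("fem_sweep.csv", "speeds.csv", "morphometry.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop("missing run outputs in ", out_dir, ": ", paste(missing, collapse = ", "))
  }
  sweep <- read.csv(file.path(out_dir, "fem_sweep.csv"))
  speeds <- read.csv(file.path(out_dir, "speeds.csv"))
  morpho <- read.csv(file.path(out_dir, "morphometry.csv"))
  refs <- list(
    matrigel40_low = c(speed = 29.5, area = 1340, ar = 10.4),
    matrigel40_high = c(speed = 7.6, area = 400, ar = 1.6),
    glass = c(speed = 28.2, area = 2309, ar = 2.2)
  )
  lines <- c("Reproduction report", "===================", "",
             "FEM height sweep (stiffness vs gel height):")
  k200 <- sweep$stiffness_N_per_m[which.max(sweep$height_um)]
  lines <- c(lines, sprintf(
    "  h = %6.1f um  k = %.4g N/m  (k/k_max_height = %.3f)  interface/global vM = %.4f",
    sweep$height_um, sweep$stiffness_N_per_m, sweep$stiffness_N_per_m / k200,
    sweep$interface_vm_Pa / sweep$max_vm_Pa))
  mono <- all(diff(sweep$stiffness_N_per_m) <= 1e-12)
  lines <- c(lines, sprintf("  stiffness non-increasing with height: %s",
                            ifelse(mono, "PASS", "FAIL")), "")
  for (nm in intersect(names(refs), unique(speeds$condition))) {
    s <- speeds$speed[speeds$condition == nm]
    se <- sd(s) / sqrt(length(s))
    ok <- abs(mean(s) - refs[[nm]]["speed"]) <= 2 * se
    lines <- c(lines, sprintf(
      "speed  %-16s n=%2d  mean=%5.1f um/hr (ref %5.1f)  |diff| %s 2*SE: %s",
      nm, length(s), mean(s), refs[[nm]]["speed"],
      ifelse(ok, "<=", ">"), ifelse(ok, "PASS", "FAIL")))
  }
  lines <- c(lines, "")
  for (nm in intersect(names(refs), unique(morpho$condition))) {
    a <- morpho$area[morpho$condition == nm]
    r <- morpho$aspect_ratio[morpho$condition == nm]
    ok_a <- abs(mean(a) - refs[[nm]]["area"]) <= 2 * sd(a) / sqrt(length(a))
    ok_r <- abs(mean(r) - refs[[nm]]["ar"]) <= 2 * sd(r) / sqrt(length(r))
    lines <- c(lines, sprintf(
      "morpho %-16s n=%2d  area=%6.0f (ref %4.0f): %s   AR=%5.2f (ref %4.1f): %s",
      nm, length(a), mean(a), refs[[nm]]["area"], ifelse(ok_a, "PASS", "FAIL"),
      mean(r), refs[[nm]]["ar"], ifelse(ok_r, "PASS", "FAIL")))
  }
  f <- file.path(out_dir, "stats.csv")
  if (file.exists(f)) {
    st <- read.csv(f)
    lines <- c(lines, "", "Group comparisons:")
    lines <- c(lines, sprintf("  %-20s %-40s p = %.3g", st$test_name, st$groups,
                              st$p_value))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}
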