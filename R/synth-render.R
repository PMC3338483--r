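# Rasterization of synthetic fluorescence images: morphology planes (filled
# ellipses with prescribed area and aspect ratio) and time-lapse frames
# (disk-shaped labelled cells over a static speckle background that carries
# the drift signal, as gel debris does in real movies).

.BG <- 0.10   # background intensity
.FG <- 0.80   # cell foreground intensity

# quantize intensities to the 16-bit grid used on disk so that an image
# written as 16-bit TIFF and re-read is bit-identical to the in-memory array
.quantize16 <- function(img) {
  round(pmin(pmax(img, 0), 1) * 65535) / 65535
}

# pixel set of a filled rotated ellipse; centre (cx, cy) and semi-axes in px.
# A pixel belongs to the ellipse when at least half of a 3x3 subsample grid
# falls inside (approximate area coverage), which keeps rasterized areas and
# second moments close to the analytic ellipse even for thin shapes.
# Returns cbind(row, col).
.ellipse_pixels <- function(cx, cy, a, b, phi, shape) {
  ext <- max(a, b) + 1
  rows <- max(1L, floor(cy - ext)):min(shape[1], ceiling(cy + ext))
  cols <- max(1L, floor(cx - ext)):min(shape[2], ceiling(cx + ext))
  if (!length(rows) || !length(cols)) return(matrix(integer(0), 0, 2))
  px <- expand.grid(row = rows, col = cols)
  inside <- integer(nrow(px))
  for (ox in c(-1, 0, 1) / 3) for (oy in c(-1, 0, 1) / 3) {
    dx <- px$col + ox - cx
    dy <- px$row + oy - cy
    xr <- dx * cos(phi) + dy * sin(phi)
    yr <- -dx * sin(phi) + dy * cos(phi)
    inside <- inside + ((xr / a)^2 + (yr / b)^2 <= 1)
  }
  keep <- inside >= 5
  cbind(px$row[keep], px$col[keep])
}

#' Render a morphology plane from sampled cell shapes
#'
#' Places each cell as a filled ellipse with the sampled area and aspect
#' ratio (semi-axes from `A = pi * a * b`, `AR = a / b`), random orientation,
#' non-overlapping, and fully inside the image (a margin of one semi-major
#' axis keeps segmentation free of border truncation). Additive Gaussian
#' background noise is applied and intensities are quantized to the 16-bit
#' grid so TIFF round-trips are bit-exact.
#'
#' @param shapes A [sample_cell_shapes()] tibble (`area` um^2, `aspect_ratio`).
#' @param config An [imaging_config()].
#' @param seed Integer seed (placement, orientation, noise).
#' @param max_retries Placement attempts per cell before giving up.
#' @return A list: `image` (matrix, intensities in [0, 1]), `truth` (tibble
#'   `cell_id`, `x`, `y` centroid in um, `area` rasterized um^2,
#'   `aspect_ratio` target, `n_px`).
#' @export
render_plane <- function(shapes, config = imaging_config(), seed = 1,
                         max_retries = 500) {
  shape <- config$image_shape
  ps <- config$pixel_size
  set.seed(seed)
  img <- matrix(.BG, shape[1], shape[2])
  occupied <- matrix(FALSE, shape[1], shape[2])
  truth <- vector("list", nrow(shapes))
  if (nrow(shapes) > 0) {
    ord <- order(shapes$area * shapes$aspect_ratio, decreasing = TRUE)
    for (i in ord) {
      A_px <- shapes$area[i] / ps^2
      ar <- max(shapes$aspect_ratio[i], 1)
      a <- sqrt(A_px * ar / pi)
      b <- sqrt(A_px / (pi * ar))
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        phi <- runif(1, 0, pi)
        ext <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
        eyt <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
        if (2 * ext + 4 >= shape[2] || 2 * eyt + 4 >= shape[1]) next
        cx <- runif(1, ext + 2, shape[2] - ext - 2)
        cy <- runif(1, eyt + 2, shape[1] - eyt - 2)
        px <- .ellipse_pixels(cx, cy, a, b, phi, shape)
        if (nrow(px) == 0) next
        # 1-px safety halo so neighbouring cells never touch 8-connectively
        halo <- unique(rbind(px,
          cbind(pmin(px[, 1] + 1, shape[1]), px[, 2]),
          cbind(pmax(px[, 1] - 1, 1), px[, 2]),
          cbind(px[, 1], pmin(px[, 2] + 1, shape[2])),
          cbind(px[, 1], pmax(px[, 2] - 1, 1))))
        if (any(occupied[halo])) next
        img[px] <- .FG
        occupied[halo] <- TRUE
        truth[[i]] <- tibble::tibble(
          cell_id = shapes$cell_id[i],
          x = mean(px[, 2]) * ps, y = mean(px[, 1]) * ps,
          area = nrow(px) * ps^2, aspect_ratio = ar, n_px = nrow(px))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place cell ", shapes$cell_id[i], " without overlap ",
             "after ", max_retries, " tries; use fewer or smaller cells, or a ",
             "larger image")
      }
    }
  }
  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                        shape[1], shape[2])
  }
  truth <- if (nrow(shapes)) dplyr::bind_rows(truth) else
    tibble::tibble(cell_id = integer(0), x = numeric(0), y = numeric(0),
                   area = numeric(0), aspect_ratio = numeric(0),
                   n_px = integer(0))
  list(image = .quantize16(img), truth = truth)
}

# static speckle background (gel debris) used by time-lapse rendering; the
# speckles translate with the drift and give registration its signal.
.speckle_field <- function(n_speckles, shape, seed) {
  set.seed(seed)
  tibble::tibble(
    x = runif(n_speckles, 3, shape[2] - 3),
    y = runif(n_speckles, 3, shape[1] - 3),
    r = runif(n_speckles, 1, 2.2),
    amp = runif(n_speckles, 0.25, 0.45)
  )
}

.draw_disks <- function(img, x_px, y_px, r_px, value, add = FALSE) {
  shape <- dim(img)
  for (i in seq_along(x_px)) {
    px <- .ellipse_pixels(x_px[i], y_px[i], r_px[i], r_px[i], 0, shape)
    if (nrow(px)) {
      if (add) img[px] <- img[px] + value[i] else img[px] <- value[i]
    }
  }
  img
}

#' Render a time-lapse movie from (drifted) tracks
#'
#' Each frame shows the labelled cells as bright disks at their current
#' (drift-included) positions over a static speckle background that is
#' translated by the same drift, emulating fluorescent debris in the gel --
#' the image content a registration algorithm actually locks onto. Gaussian
#' noise is added per frame.
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y` in um), typically
#'   the drifted tracks from [apply_drift()].
#' @param config An [imaging_config()].
#' @param drift Optional drift tibble from [apply_drift()]; when supplied the
#'   speckle background translates by it (cells must already contain it).
#' @param cell_radius Rendered cell radius (um); cell-sized per the study system (10 um diameter).
#' @param n_speckles Number of background speckles.
#' @param seed Integer seed (speckle field + noise).
#' @return List of frame matrices (intensities in [0, 1], 16-bit quantized).
#' @export
render_track_frames <- function(tracks, config = imaging_config(), drift = NULL,
                                cell_radius = 5, n_speckles = 400, seed = 1) {
  shape <- config$image_shape
  ps <- config$pixel_size
  nf <- max(tracks$frame)
  speckles <- .speckle_field(n_speckles, shape, seed + 1L)
  set.seed(seed)
  frames <- vector("list", nf)
  for (k in seq_len(nf)) {
    img <- matrix(.BG, shape[1], shape[2])
    off <- if (is.null(drift)) c(0, 0) else
      c(drift$dx[drift$frame == k], drift$dy[drift$frame == k])
    img <- .draw_disks(img, (speckles$x + off[1] / ps),
                       (speckles$y + off[2] / ps), speckles$r,
                       .BG + speckles$amp)
    sub <- tracks[tracks$frame == k, ]
    img <- .draw_disks(img, sub$x / ps, sub$y / ps,
                       rep(cell_radius / ps, nrow(sub)),
                       rep(.FG, nrow(sub)))
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                          shape[1], shape[2])
    }
    frames[[k]] <- .quantize16(img)
  }
  frames
}

#' Write a synthetic dataset to disk
#'
#' Images go to multi-page 16-bit TIFF (one page per z-plane or time frame);
#' truth tables to CSV; acquisition metadata (pixel size, z positions, frame
#' interval) to a YAML sidecar. Re-reading a stack with [read_stack()]
#' reproduces the pixel arrays bit-exactly.
#'
#' @param images List of image matrices (values in [0, 1]).
#' @param truth Truth tibble/data.frame (or a named list of them).
#' @param out_dir Output directory (created if needed).
#' @param stem File stem, e.g. `"matrigel40_low"`.
#' @param metadata Named list written to `<stem>_meta.yaml`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(images, truth, out_dir, stem, metadata = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  files <- character(0)
  tif <- file.path(out_dir, paste0(stem, ".tif"))
  tiff::writeTIFF(images, tif, bits.per.sample = 16L)
  files["images"] <- tif
  if (is.data.frame(truth)) truth <- list(truth = truth)
  for (nm in names(truth)) {
    f <- file.path(out_dir, paste0(stem, "_", nm, ".csv"))
    write.csv(truth[[nm]], f, row.names = FALSE)
    files[nm] <- f
  }
  if (length(metadata)) {
    f <- file.path(out_dir, paste0(stem, "_meta.yaml"))
    yaml::write_yaml(metadata, f)
    files["metadata"] <- f
  }
  invisible(files)
}

#' Read a multi-page TIFF stack written by [write_dataset()]
#'
#' @param path TIFF file path.
#' @return List of image matrices with values in [0, 1].
#' @export
read_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  imgs
}
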