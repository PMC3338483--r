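# Per-plane segmentation and shape measurement of labelled cells. Automated
# stand-in for interactive ImageJ analysis: global Otsu threshold, connected
# components (8-connectivity), size filter, border exclusion, and
# moment-equivalent ellipse fitting.

# merge 4-connected labels that touch diagonally so components follow
# 8-connectivity (EBImage::bwlabel is 4-connected)
.merge_diagonal_labels <- function(lab) {
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) apply(unique(pairs), 1, function(p) unite(p[1], p[2]))
  roots <- vapply(seq_len(n), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment labelled cells in a single plane
#'
#' Global threshold (Otsu by default) -> connected components
#' (8-connectivity) -> discard regions smaller than `min_area` and regions
#' touching the image border. Region labels are dense from 1.
#'
#' @param image Single-channel image matrix (intensities in [0, 1]).
#' @param pixel_size Pixel size (um/px).
#' @param min_area Minimum region area (um^2) kept; also serves as the
#'   in-focus proxy (out-of-focus cells are dim and fragment below it).
#' @param threshold `"otsu"` or a numeric threshold on intensity.
#' @return A list of regions, each a list with `label`, `px` (n x 2 matrix of
#'   row/col pixel coordinates), `n_px`, `area` (um^2), `centroid` (x, y um),
#'   `touches_border`. An empty image yields an empty list.
#' @export
segment_plane <- function(image, pixel_size = 1, min_area = 50,
                          threshold = "otsu") {
  stopifnot(is.matrix(image), pixel_size > 0)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    stopifnot(is.numeric(threshold))
    threshold
  }
  mask <- image > thr
  if (!any(mask)) return(list())
  lab <- .merge_diagonal_labels(EBImage::bwlabel(mask))
  nr <- nrow(image); nc <- ncol(image)
  idx <- which(lab > 0)
  by_label <- split(idx, lab[idx])
  regions <- list()
  for (ids in by_label) {
    px <- cbind((ids - 1L) %% nr + 1L, (ids - 1L) %/% nr + 1L)
    area <- nrow(px) * pixel_size^2
    if (area < min_area) next
    if (any(px[, 1] == 1 | px[, 1] == nr | px[, 2] == 1 | px[, 2] == nc)) next
    regions[[length(regions) + 1L]] <- list(
      label = length(regions) + 1L,
      px = px,
      n_px = nrow(px),
      area = area,
      centroid = c(x = mean(px[, 2]) * pixel_size,
                   y = mean(px[, 1]) * pixel_size),
      touches_border = FALSE
    )
  }
  regions
}

#' Area of a segmented region
#'
#' @param region A region from [segment_plane()].
#' @param pixel_size Pixel size (um/px).
#' @return Area in um^2 (pixel count x pixel_size^2).
#' @export
measure_area <- function(region, pixel_size = 1) {
  nrow(region$px) * pixel_size^2
}

#' Aspect ratio of the moment-equivalent ellipse of a region
#'
#' Ratio of major to minor axis of the ellipse with the same second central
#' moments as the pixel region; >= 1 by construction and invariant to
#' rotation and pixel size.
#'
#' @param region A region from [segment_plane()] (>= 5 px).
#' @param max_ar Cap reported for degenerate (collinear) regions.
#' @return Aspect ratio (dimensionless).
#' @export
ellipse_aspect_ratio <- function(region, max_ar = 100) {
  px <- region$px
  if (nrow(px) < 5) stop("region too small (< 5 px) for an ellipse fit")
  y <- px[, 1] - mean(px[, 1])
  x <- px[, 2] - mean(px[, 2])
  # 1/12: second moment of the unit pixel itself (continuity correction)
  mxx <- mean(x^2) + 1 / 12; myy <- mean(y^2) + 1 / 12; mxy <- mean(x * y)
  tr <- (mxx + myy) / 2
  det <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + det
  l2 <- tr - det
  if (l2 <= .Machine$double.eps * l1) return(max_ar)
  min(sqrt(l1 / l2), max_ar)
}

#' Measure all regions of a plane into cell records
#'
#' @param image Image matrix.
#' @param plane_z Plane height (um).
#' @param pixel_size Pixel size (um/px).
#' @param ... Passed to [segment_plane()].
#' @return A tibble: `cell_id`, `plane_z`, `area`, `aspect_ratio`, `x`, `y`.
#' @export
measure_plane <- function(image, plane_z, pixel_size = 1, ...) {
  regions <- segment_plane(image, pixel_size = pixel_size, ...)
  if (!length(regions)) {
    return(tibble::tibble(cell_id = integer(0), plane_z = numeric(0),
                          area = numeric(0), aspect_ratio = numeric(0),
                          x = numeric(0), y = numeric(0)))
  }
  tibble::tibble(
    cell_id = vapply(regions, `[[`, integer(1), "label"),
    plane_z = plane_z,
    area = vapply(regions, measure_area, numeric(1), pixel_size = pixel_size),
    aspect_ratio = vapply(regions, ellipse_aspect_ratio, numeric(1)),
    x = vapply(regions, function(r) r$centroid[["x"]], numeric(1)),
    y = vapply(regions, function(r) r$centroid[["y"]], numeric(1))
  )
}

#' Normalize plane heights to the first plane containing cells
#'
#' Surface roughness makes the absolute z origin unreliable, so zero height
#' is set to the lowest plane in which any cell was observed. Idempotent.
#'
#' @param records Cell-record tibble with a `plane_z` column.
#' @return The records with `plane_z` shifted so the lowest populated plane
#'   is 0.
#' @export
normalize_height_origin <- function(records) {
  if (nrow(records) == 0) stop("no cells observed in any plane")
  records$plane_z <- records$plane_z - min(records$plane_z)
  records
}

#' Per-height-bin summary of a cell metric
#'
#' @param records Cell-record tibble (`plane_z` plus the metric column).
#' @param bin_edges Strictly increasing bin edges (um). Defaults follow the
#'   reporting landmarks of the study system: 0-50, 50-100, 100-200, 200-500,
#'   >500 um.
#' @param metric Column to summarize (`"area"` or `"aspect_ratio"`).
#' @return A `height_profile` tibble: `z` (mean plane height of the cells in
#'   the bin), `bin`, `n`, `mean`, `sd` (sample sd; 0 with `low_n = TRUE` for
#'   singleton bins). Empty bins are omitted.
#' @export
profile_by_height <- function(records, bin_edges = c(0, 50, 100, 200, 500, Inf),
                              metric = "area") {
  stopifnot(all(diff(bin_edges) > 0), metric %in% names(records))
  bin <- cut(records$plane_z, bin_edges, include.lowest = TRUE, right = FALSE)
  keep <- !is.na(bin)
  vals <- records[[metric]][keep]
  zs <- records$plane_z[keep]
  bin <- droplevels(bin[keep])
  out <- lapply(levels(bin), function(b) {
    v <- vals[bin == b]
    tibble::tibble(z = mean(zs[bin == b]), bin = b, n = length(v),
                   mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
                   low_n = length(v) < 2)
  })
  out <- dplyr::bind_rows(out)
  out <- out[order(out$z), ]
  class(out) <- c("height_profile", class(out))
  out
}

#' Fit an exponential decay to a height profile
#'
#' Least-squares fit of `m(z) = m_bulk + (m0 - m_bulk) * exp(-z / lambda)`
#' with `lambda > 0` constrained (Levenberg-Marquardt with box bounds).
#' Effectively flat profiles are flagged as degenerate (`lambda`
#' unidentifiable) and return the mean as `m_bulk`.
#'
#' @param profile A [profile_by_height()] tibble (>= 4 bins for a fit).
#' @param flat_tol Relative range below which the profile is declared flat.
#' @return A list: `m0`, `m_bulk`, `lambda` (um), `residual_norm`,
#'   `degenerate`.
#' @export
fit_exponential_profile <- function(profile, flat_tol = 1e-3) {
  stopifnot(all(c("z", "mean") %in% names(profile)))
  z <- profile$z
  m <- profile$mean
  if (diff(range(m)) <= flat_tol * max(abs(m))) {
    return(list(m0 = mean(m), m_bulk = mean(m), lambda = NA_real_,
                residual_norm = sqrt(sum((m - mean(m))^2)), degenerate = TRUE))
  }
  if (length(z) < 4) stop("need >= 4 bins to fit the exponential profile")
  # lambda = exp(rho) keeps the decay length positive without box bounds
  start <- list(m0 = m[which.min(z)], m_bulk = m[which.max(z)],
                rho = log(max(diff(range(z)) / 3, 1)))
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ m_bulk + (m0 - m_bulk) * exp(-z * exp(-rho)),
                      data = data.frame(z = z, m = m), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential profile fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- coef(fit)
  list(m0 = unname(cf["m0"]), m_bulk = unname(cf["m_bulk"]),
       lambda = exp(unname(cf["rho"])),
       residual_norm = sqrt(sum(stats::residuals(fit)^2)), degenerate = FALSE)
}
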