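# Drift registration, detection linking and migration-speed computation.
# Registration is translation-only (cross-correlation peak with subpixel
# parabolic refinement), matching how time-lapse stacks of drifting gels are
# aligned before manual tracking.

# circular cross-correlation shift of `cur` relative to `ref` (both demeaned)
# via FFT; returns c(dx, dy) in px such that cur ~ ref shifted by (dx, dy).
.xcorr_shift <- function(ref, cur) {
  a <- ref - mean(ref)
  b <- cur - mean(cur)
  if (sd(a) < 1e-12 || sd(b) < 1e-12) return(c(0, 0, flat = 1))
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(cc); nc <- ncol(cc)
  sub <- function(m, i, j) m[(i - 1) %% nr + 1, (j - 1) %% nc + 1]
  para <- function(l, c0, r) {
    den <- l - 2 * c0 + r
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (l - r) / den
  }
  di <- para(sub(cc, pk[1] - 1, pk[2]), cc[pk[1], pk[2]], sub(cc, pk[1] + 1, pk[2]))
  dj <- para(sub(cc, pk[1], pk[2] - 1), cc[pk[1], pk[2]], sub(cc, pk[1], pk[2] + 1))
  # unwrap periodic peak position to signed shift
  si <- pk[1] - 1 + di; if (si > nr / 2) si <- si - nr
  sj <- pk[2] - 1 + dj; if (sj > nc / 2) sj <- sj - nc
  # the unwrapped peak sits at the content drift of cur relative to ref;
  # the registration offset is its negation (the correction aligning cur
  # back onto ref)
  c(sj, si, flat = 0)
}

#' Register a frame series for global translation drift
#'
#' Estimates per-frame translation offsets by FFT cross-correlation of each
#' frame against the first, with subpixel parabolic peak refinement. The
#' static gel texture anchors the correlation peak even though individual
#' cells move. The returned offset of frame k is the translation that,
#' applied to frame k's content (or added to its detection coordinates),
#' aligns it with frame 1 -- i.e. the negative of the drift.
#'
#' @param frames List of >= 2 image matrices with a common size.
#' @return A list: `offsets` (tibble `frame`, `dx_px`, `dy_px`), `corrected`
#'   (frames rolled by the rounded offsets, background filled with the frame
#'   median).
#' @export
register_frames <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 2)
  nf <- length(frames)
  off <- matrix(0, nf, 2)
  for (k in 2:nf) {
    s <- .xcorr_shift(frames[[1]], frames[[k]])
    if (s[["flat"]] == 1) {
      warning("frame ", k, " is featureless; assuming zero offset")
      s[1:2] <- 0
    }
    off[k, ] <- s[1:2]
  }
  corrected <- lapply(seq_len(nf), function(k) {
    .roll_image(frames[[k]], round(off[k, 1]), round(off[k, 2]))
  })
  list(offsets = tibble::tibble(frame = seq_len(nf),
                                dx_px = off[, 1], dy_px = off[, 2]),
       corrected = corrected)
}

# integer-shift an image by (dx, dy) px (x: columns, y: rows), filling
# exposed borders with the image median.
.roll_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(median(img), nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: closest pairs are
#' linked first, each detection is used at most once, and links longer than
#' `max_step` are forbidden. Unlinked detections start new tracks; tracks
#' observed in fewer than `min_frac` of all frames are dropped (no gap
#' closing -- a missed detection splits the track).
#'
#' @param detections Tibble with `frame`, `x`, `y` (um).
#' @param max_step Maximum link length (um) per frame interval.
#' @param min_frac Minimum fraction of frames a track must span to be kept.
#' @return A `track_table` tibble: `cell_id`, `frame`, `x`, `y`.
#' @export
link_detections <- function(detections, max_step, min_frac = 0.8) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)), max_step > 0)
  frames <- sort(unique(detections$frame))
  nf <- length(frames)
  det <- detections[order(detections$frame), c("frame", "x", "y")]
  det$track <- NA_integer_
  next_id <- 0L
  prev_idx <- which(det$frame == frames[1])
  det$track[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx)
  for (k in 2:nf) {
    cur_idx <- which(det$frame == frames[k])
    if (!length(cur_idx)) { prev_idx <- cur_idx; next }
    # a missing frame breaks all links: gaps split tracks (no gap closing)
    if (frames[k] != frames[k - 1] + 1) prev_idx <- integer(0)
    if (length(prev_idx)) {
      d <- outer(det$x[prev_idx], det$x[cur_idx], "-")^2 +
           outer(det$y[prev_idx], det$y[cur_idx], "-")^2
      d <- sqrt(d)
      repeat {
        m <- which.min(d)
        if (!length(m) || d[m] > max_step) break
        i <- (m - 1) %% length(prev_idx) + 1
        j <- (m - 1) %/% length(prev_idx) + 1
        det$track[cur_idx[j]] <- det$track[prev_idx[i]]
        d[i, ] <- Inf
        d[, j] <- Inf
        if (all(!is.finite(d))) break
      }
    }
    new <- cur_idx[is.na(det$track[cur_idx])]
    if (length(new)) {
      det$track[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  counts <- table(det$track)
  keep <- as.integer(names(counts)[counts >= min_frac * nf])
  det <- det[det$track %in% keep, ]
  det$cell_id <- match(det$track, sort(unique(det$track)))
  tibble::tibble(cell_id = det$cell_id, frame = det$frame,
                 x = det$x, y = det$y)[order(det$cell_id, det$frame), ]
}

#' Path-length migration speed of one track
#'
#' Total length of movement divided by the observation time:
#' `sum ||p_(i+1) - p_i|| / (n_steps * frame_interval)`.
#'
#' @param track Tibble with time-ordered `x`, `y` positions (um).
#' @param frame_interval Frame interval (minutes).
#' @return Speed (um/hr).
#' @export
track_speed <- function(track, frame_interval) {
  if (nrow(track) < 2) stop("track has fewer than 2 positions")
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  hours <- (nrow(track) - 1) * frame_interval / 60
  path / hours
}

#' Descriptive speed summary over a set of tracks
#'
#' @param tracks A [link_detections()] track table.
#' @param frame_interval Frame interval (minutes).
#' @param group_label Label attached to the summary row.
#' @param min_n Minimum number of tracks before a low-n warning (the study
#'   convention is at least 15 tracked cells per condition).
#' @return A list: `summary` (tibble `group`, `n`, `mean`, `sd` in um/hr),
#'   `speeds` (per-cell tibble `cell_id`, `speed`).
#' @export
summarize_speeds <- function(tracks, frame_interval, group_label = "group",
                             min_n = 15) {
  ids <- unique(tracks$cell_id)
  if (!length(ids)) stop("no tracks to summarize")
  speeds <- vapply(ids, function(i) {
    track_speed(tracks[tracks$cell_id == i, ], frame_interval)
  }, numeric(1))
  if (length(ids) < min_n) {
    warning("only ", length(ids), " tracks (study convention is >= ", min_n, ")")
  }
  list(summary = tibble::tibble(group = group_label, n = length(ids),
                                mean = mean(speeds),
                                sd = if (length(ids) > 1) sd(speeds) else 0),
       speeds = tibble::tibble(cell_id = ids, speed = speeds))
}
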