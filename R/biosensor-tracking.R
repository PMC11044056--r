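#' Link per-frame FA detections into tracks
#'
#' Greedy nearest-centroid linking: at each frame, track heads and new
#' detections are matched in order of increasing distance, subject to a
#' maximum displacement gate per elapsed frame. Unmatched detections
#' start new tracks; a track missing for one frame may be re-acquired at
#' the next (the skipped frame is filled by linear interpolation and
#' flagged); after two missed frames a track ends.
#'
#' @param frames list of per-frame FA tables (as `segment_fas()$fas` or
#'   the per-frame rows of `generate_ratio_movie()$truth` renamed to the
#'   same columns): must contain `label`, `centroid_x_um`,
#'   `centroid_y_um` and, if available, `major_um`, `minor_um`,
#'   `orientation_rad`.
#' @param max_disp_um gate: maximum centroid displacement per frame.
#' @param bridge_gaps allow one-frame gaps.
#' @return List of `fa_track` data frames with columns `frame`, `label`
#'   (NA at interpolated frames), `centroid_x_um`, `centroid_y_um`,
#'   `length_um`, `minor_um`, `orientation_rad`, `interpolated`.
#' @export
track_fas <- function(frames, max_disp_um = 1, bridge_gaps = TRUE) {
  stopifnot(length(frames) >= 2L)
  get_col <- function(df, col, default = NA_real_)
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  mk_row <- function(df, j, t) data.frame(
    frame = t, label = df$label[j],
    centroid_x_um = df$centroid_x_um[j],
    centroid_y_um = df$centroid_y_um[j],
    length_um = get_col(df, "major_um")[j],
    minor_um = get_col(df, "minor_um")[j],
    orientation_rad = get_col(df, "orientation_rad")[j],
    interpolated = FALSE)
  tracks <- list()     # each: list(rows = data.frame, last_frame)
  open <- integer(0)   # indices into tracks that are still active
  for (t in seq_along(frames)) {
    det <- frames[[t]]
    n_det <- if (is.null(det)) 0L else nrow(det)
    assigned_det <- rep(FALSE, max(n_det, 0L))
    if (length(open) && n_det) {
      heads <- do.call(rbind, lapply(open, function(i) {
        r <- tracks[[i]]$rows
        data.frame(track = i, last = tracks[[i]]$last_frame,
                   x = r$centroid_x_um[nrow(r)], y = r$centroid_y_um[nrow(r)])
      }))
      cand <- expand.grid(h = seq_len(nrow(heads)), d = seq_len(n_det))
      cand$dist <- sqrt(
        (heads$x[cand$h] - det$centroid_x_um[cand$d])^2 +
        (heads$y[cand$h] - det$centroid_y_um[cand$d])^2)
      cand$gate <- max_disp_um * (t - heads$last[cand$h])
      cand <- cand[cand$dist <= cand$gate, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_h <- logical(nrow(heads))
      for (r in seq_len(nrow(cand))) {
        h <- cand$h[r]; d <- cand$d[r]
        if (used_h[h] || assigned_det[d]) next
        used_h[h] <- TRUE; assigned_det[d] <- TRUE
        ti <- heads$track[h]
        new_row <- mk_row(det, d, t)
        if (t - heads$last[h] == 2L) {   # bridge the skipped frame
          prev <- tracks[[ti]]$rows[nrow(tracks[[ti]]$rows), ]
          mid <- new_row
          mid$frame <- t - 1L; mid$label <- NA_integer_
          mid$interpolated <- TRUE
          num_cols <- c("centroid_x_um", "centroid_y_um", "length_um",
                        "minor_um", "orientation_rad")
          mid[num_cols] <- (prev[num_cols] + new_row[num_cols]) / 2
          tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows, mid)
        }
        tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows, new_row)
        tracks[[ti]]$last_frame <- t
      }
    }
    if (n_det) for (d in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(rows = mk_row(det, d, t),
                                            last_frame = t)
    }
    max_gap <- if (bridge_gaps) 2L else 1L
    open <- which(vapply(tracks, function(tr) t - tr$last_frame < max_gap |
                           tr$last_frame == t, TRUE))
    open <- open[vapply(tracks[open], function(tr)
      t - tr$last_frame <= (max_gap - 1L), TRUE)]
  }
  out <- lapply(seq_along(tracks), function(i) {
    r <- tracks[[i]]$rows
    attr(r, "track_id") <- i
    class(r) <- c("fa_track", "data.frame")
    r
  })
  out
}

#' Boxcar smoothing (-/+1 time point)
#'
#' Each element is replaced by the mean of itself and its immediate
#' neighbours; the window shrinks at the edges. `NA` values are dropped
#' from the window mean.
#'
#' @param series numeric vector.
#' @return Smoothed vector of the same length.
#' @examples
#' boxcar_smooth(c(1, 2, 3))        # 1.5 2.0 2.5
#' boxcar_smooth(c(0, 0, 3, 0, 0))  # 0 1 1 1 0
#' @export
boxcar_smooth <- function(series) {
  n <- length(series)
  if (n == 0L) return(series)
  vapply(seq_len(n), function(i) {
    w <- series[max(1L, i - 1L):min(n, i + 1L)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
}

#' Per-FA ratiometric time series
#'
#' For each frame of a track, the ratio of summed numerator to summed
#' denominator intensity over the FA pixels (sum/sum, robust to pixel
#' noise), followed by boxcar smoothing. Channels should be
#' background-subtracted; pass `background_radius` to apply rolling-ball
#' subtraction here. The FA pixel set comes from the per-frame label
#' rasters when given, else from the track's ellipse-equivalent region.
#'
#' @param movie an [fa_movie()].
#' @param track an `fa_track` from [track_fas()].
#' @param labels_by_frame optional list of label rasters, one per movie
#'   frame, whose labels match `track$label`.
#' @param background_radius optional rolling-ball radius (px) applied to
#'   both channels before summing.
#' @return A `ratio_series` object: `track_id`, `times_s`, `raw_ratio`,
#'   `smoothed_ratio`, `interpolated`.
#' @export
compute_ratio_series <- function(movie, track, labels_by_frame = NULL,
                                 background_radius = NULL) {
  stopifnot(inherits(movie, "fa_movie"))
  ps <- movie$pixel_size_um
  raw <- rep(NA_real_, nrow(track))
  for (i in seq_len(nrow(track))) {
    t <- track$frame[i]
    num <- movie$numerator[, , t]; den <- movie$denominator[, , t]
    if (!is.null(background_radius)) {
      num <- subtract_background(num, background_radius)
      den <- subtract_background(den, background_radius)
    }
    mask <- fa_pixel_mask(track, i, labels_by_frame, dim(num), ps)
    if (!any(mask)) next
    dsum <- sum(den[mask])
    if (dsum > 0) raw[i] <- sum(num[mask]) / dsum
  }
  # bridge NA at interpolated frames linearly where neighbours exist
  interp <- track$interpolated | is.na(raw)
  if (anyNA(raw)) {
    ok <- which(!is.na(raw))
    if (length(ok) >= 2L) {
      nas <- which(is.na(raw))
      inner <- nas[nas > min(ok) & nas < max(ok)]
      if (length(inner))
        raw[inner] <- stats::approx(ok, raw[ok], xout = inner)$y
    }
  }
  structure(list(track_id = attr(track, "track_id"),
                 times_s = numeric(0), raw_ratio = raw,
                 smoothed_ratio = boxcar_smooth(raw),
                 frames = track$frame,
                 interpolated = interp),
            class = "ratio_series") -> rs
  rs$times_s <- (track$frame - 1) * movie$frame_interval_s
  rs
}

fa_pixel_mask <- function(track, i, labels_by_frame, dims, pixel_size_um) {
  t <- track$frame[i]
  if (!is.null(labels_by_frame) && !is.na(track$label[i]))
    return(labels_by_frame[[t]] == track$label[i])
  # ellipse-equivalent region from the track geometry
  cx <- track$centroid_x_um[i] / pixel_size_um + 0.5
  cy <- track$centroid_y_um[i] / pixel_size_um + 0.5
  a <- track$length_um[i] / 2 / pixel_size_um
  b <- max(track$minor_um[i], pixel_size_um) / 2 / pixel_size_um
  th <- track$orientation_rad[i]
  x <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE) - cx
  y <- -(matrix(seq_len(dims[1L]), dims[1L], dims[2L]) - cy)
  u <- x * cos(th) + y * sin(th); v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' @export
print.ratio_series <- function(x, ...) {
  cat(sprintf("ratio_series (track %s): %d frames, raw ratio %.3f-%.3f\n",
              as.character(x$track_id), length(x$raw_ratio),
              min(x$raw_ratio, na.rm = TRUE),
              max(x$raw_ratio, na.rm = TRUE)))
  invisible(x)
}
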