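#' Isolate, vertically align and register an FA across frames
#'
#' Crops a patch around the FA at every frame of a track, rotates it so
#' the major axis is vertical with the distal end (the axis endpoint
#' farther from the cell centroid) pointing up, and registers frames on
#' the FA centroid. The per-pixel ratio (numerator/denominator) is
#' sampled bilinearly on the aligned grid and masked to the FA's
#' ellipse-equivalent region (`NA` outside).
#'
#' Near-circular frames (aspect ratio below `min_aspect`) have no
#' reliable axis: their orientation is carried over from the previous
#' frame; if the first frame is near-circular the patch stack cannot be
#' oriented and this is an error.
#'
#' @param movie an [fa_movie()].
#' @param track an `fa_track` with geometry columns (`length_um`,
#'   `minor_um`, `orientation_rad`).
#' @param cell_centroid_px cell centroid `(x, y)` in pixels, used to
#'   decide which axis end is distal.
#' @param min_aspect aspect ratio below which a frame is treated as
#'   near-circular.
#' @param background_radius optional rolling-ball radius applied to both
#'   channels before the ratio is formed.
#' @return An `aligned_fa` object: `patches` (list of ratio matrices,
#'   distal end at row 1), `length_px` per frame, `centre_row`,
#'   `centre_col`, `times_s`, `axis_angles_rad`.
#' @export
register_fa_patch <- function(movie, track, cell_centroid_px,
                              min_aspect = 1.2, background_radius = NULL) {
  stopifnot(inherits(movie, "fa_movie"))
  ps <- movie$pixel_size_um
  n <- nrow(track)
  max_len_px <- max(track$length_um, na.rm = TRUE) / ps
  half_h <- ceiling(max_len_px * 0.75)
  half_w <- max(3L, ceiling(max_len_px * 0.4))
  H <- 2L * half_h + 1L; W <- 2L * half_w + 1L
  patches <- vector("list", n)
  angles <- numeric(n)
  prev_e <- NULL
  for (i in seq_len(n)) {
    t <- track$frame[i]
    num <- movie$numerator[, , t]; den <- movie$denominator[, , t]
    if (!is.null(background_radius)) {
      num <- subtract_background(num, background_radius)
      den <- subtract_background(den, background_radius)
    }
    cx <- track$centroid_x_um[i] / ps + 0.5
    cy <- track$centroid_y_um[i] / ps + 0.5
    a <- track$length_um[i] / 2 / ps
    b <- max(track$minor_um[i] / 2 / ps, 0.5)
    aspect <- track$length_um[i] / max(track$minor_um[i], 1e-9)
    if (aspect >= min_aspect || is.null(prev_e)) {
      if (aspect < min_aspect)
        stop("first frame of track is near-circular (aspect < ",
             min_aspect, "); axis orientation undefined")
      th <- track$orientation_rad[i]
      # axis direction in image coords (x right, y down); y-up angle th
      e <- c(cos(th), -sin(th))
      # distal end: farther from the cell centroid
      dp <- sum((c(cx, cy) + a * e - cell_centroid_px)^2)
      dm <- sum((c(cx, cy) - a * e - cell_centroid_px)^2)
      if (dm > dp) e <- -e
      # keep direction continuous with the previous frame
      if (!is.null(prev_e) && sum(e * prev_e) < 0 &&
          abs(dp - dm) < 1e-6) e <- -e
    } else {
      e <- prev_e
    }
    prev_e <- e
    w <- c(-e[2L], e[1L])   # perpendicular, completes the patch frame
    # patch row r: v = half_h + 1 - r (distal up); col c: u = c - centre
    v <- half_h + 1L - seq_len(H)
    u <- seq_len(W) - (half_w + 1L)
    xs <- cx + outer(v * e[1L], u * w[1L], "+")
    ys <- cy + outer(v * e[2L], u * w[2L], "+")
    rn <- bilinear_sample(num, as.vector(xs), as.vector(ys))
    rd <- bilinear_sample(den, as.vector(xs), as.vector(ys))
    ratio <- ifelse(is.finite(rd) & rd > 0, rn / rd, NA_real_)
    patch <- matrix(ratio, H, W)
    # mask to the ellipse-equivalent region (axis coords are the grid)
    vm <- matrix(v, H, W); um <- matrix(rep(u, each = H), H, W)
    patch[(vm / a)^2 + (um / b)^2 > 1] <- NA_real_
    patches[[i]] <- patch
    angles[i] <- atan2(-e[2L], e[1L])
  }
  structure(list(patches = patches,
                 length_px = track$length_um / ps,
                 centre_row = half_h + 1L, centre_col = half_w + 1L,
                 times_s = numeric(0),
                 frames = track$frame,
                 axis_angles_rad = angles),
            class = "aligned_fa") -> al
  al$times_s <- (track$frame - 1) * movie$frame_interval_s
  al
}

#' Build a sub-FA kymograph from aligned patches
#'
#' For every frame, the ratio is averaged across `line_width_px` columns
#' centred on the FA axis at each of `n_positions` normalized axis
#' positions (0 = medial end, 1 = distal end of the *current* FA
#' length), giving a position x time matrix of biosensor ratio.
#'
#' @param aligned an `aligned_fa` from [register_fa_patch()].
#' @param line_width_px width of the averaging line in pixels.
#' @param n_positions number of axis samples.
#' @return A `kymograph` object: `ratio` (position x time),
#'   `positions` (0..1), `times_s`.
#' @export
build_kymograph <- function(aligned, line_width_px = 3L,
                            n_positions = 25L) {
  stopifnot(inherits(aligned, "aligned_fa"))
  nt <- length(aligned$patches)
  if (nt < 2L) stop("need at least 2 aligned frames")
  pos <- seq(0, 1, length.out = n_positions)
  half_w <- (max(1L, as.integer(line_width_px)) - 1L) %/% 2L
  cols <- (aligned$centre_col - half_w):(aligned$centre_col + half_w)
  mat <- matrix(NA_real_, n_positions, nt)
  for (t in seq_len(nt)) {
    p <- aligned$patches[[t]]
    cols_t <- cols[cols >= 1L & cols <= ncol(p)]
    L <- aligned$length_px[t]
    # axis position pos -> patch row (distal = pos 1 = top)
    v <- (pos - 0.5) * L
    rows <- aligned$centre_row - v
    for (j in seq_len(n_positions)) {
      r0 <- rows[j]
      vals <- bilinear_sample(p, cols_t, rep(r0, length(cols_t)))
      if (any(is.finite(vals))) mat[j, t] <- mean(vals, na.rm = TRUE)
    }
  }
  structure(list(ratio = mat, positions = pos, times_s = aligned$times_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d positions x %d frames, ratio %.3f-%.3f\n",
              nrow(x$ratio), ncol(x$ratio),
              min(x$ratio, na.rm = TRUE), max(x$ratio, na.rm = TRUE)))
  invisible(x)
}

#' Plot a kymograph
#'
#' @param x a `kymograph`.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = x$times_s, y = x$positions, z = t(x$ratio),
                  xlab = "time (s)", ylab = "axis position (medial 0 - distal 1)",
                  ...)
  invisible(x)
}

#' Locate the peak of PKA activity along the FA axis
#'
#' Finds the global maximum of the kymograph ratio matrix and maps its
#' axis position onto thirds: `[0, 1/3)` medial, `[1/3, 2/3)` central,
#' `[2/3, 1]` distal. Ties across cells of the matrix are broken by the
#' earliest time, then the larger (more distal) position; a tie event is
#' recorded in the result.
#'
#' @param kym a `kymograph`.
#' @return List: `third` (`"medial"`, `"central"` or `"distal"`),
#'   `position`, `time_s`, `value`, `tie` (logical).
#' @export
score_peak_location <- function(kym) {
  stopifnot(inherits(kym, "kymograph"))
  m <- kym$ratio
  if (all(!is.finite(m))) stop("kymograph has no finite values")
  mx <- max(m[is.finite(m)])
  hits <- which(m == mx, arr.ind = TRUE)
  tie <- nrow(hits) > 1L
  # earliest time, then larger position
  hits <- hits[order(hits[, 2L], -kym$positions[hits[, 1L]]), ,
               drop = FALSE]
  p <- kym$positions[hits[1L, 1L]]
  third <- if (p < 1 / 3) "medial" else if (p < 2 / 3) "central" else
    "distal"
  list(third = third, position = p,
       time_s = kym$times_s[hits[1L, 2L]], value = mx, tie = tie)
}
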