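#' Movie specification for synthetic biosensor time-lapses
#'
#' Describes a two-channel ratiometric biosensor movie built on a
#' [scene_spec()]: the denominator channel tracks FA geometry (abundance
#' reference), the numerator is the denominator modulated by a planted
#' activity field. Per FA, the activity is uniform or carries a Gaussian
#' hot spot centred in the distal, central or medial third of the major
#' axis (distal = the end farther from the cell centroid); the major
#' axis grows or shrinks linearly at `growth_rate_um_per_min`; an
#' optional inhibitor step multiplies activity by `1 - ratio_drop`
#' during `[frame_on, frame_off)`.
#'
#' Typical acquisition regimes are 3 frames/min (`frame_interval_s =
#' 20`) for dynamics and one frame every 3 s for 1 min
#' (`frame_interval_s = 3, n_frames = 21`) for sub-FA kymographs.
#'
#' @param scene a [scene_spec()].
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param activity_pattern per-FA pattern, recycled: one of `"uniform"`,
#'   `"distal_hotspot"`, `"central_hotspot"`, `"medial_hotspot"`.
#' @param growth_rate_um_per_min per-FA linear length change, recycled.
#' @param hotspot_amp hot-spot amplitude above the baseline activity of
#'   1 (so the peak ratio is `1 + hotspot_amp`).
#' @param hotspot_sigma hot-spot width as a fraction of FA length.
#' @param base_ratio baseline numerator/denominator ratio.
#' @param inhibitor_step optional list `(frame_on, frame_off,
#'   ratio_drop)` with `ratio_drop` in `(0, 1]`.
#' @return A `movie_spec` object.
#' @export
movie_spec <- function(scene, n_frames = 20L, frame_interval_s = 20,
                       activity_pattern = "uniform",
                       growth_rate_um_per_min = 0,
                       hotspot_amp = 1, hotspot_sigma = 0.12,
                       base_ratio = 1, inhibitor_step = NULL) {
  stopifnot(inherits(scene, "scene_spec"))
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  nfa <- length(scene$fa_specs)
  patterns <- c("uniform", "distal_hotspot", "central_hotspot",
                "medial_hotspot")
  activity_pattern <- rep_len(match.arg(activity_pattern, patterns,
                                        several.ok = TRUE), nfa)
  growth_rate_um_per_min <- rep_len(growth_rate_um_per_min, nfa)
  if (!is.null(inhibitor_step)) {
    stopifnot(all(c("frame_on", "frame_off", "ratio_drop") %in%
                    names(inhibitor_step)))
    if (inhibitor_step$ratio_drop <= 0 || inhibitor_step$ratio_drop > 1)
      stop("ratio_drop must be in (0, 1]")
  }
  structure(list(scene = scene, n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 activity_pattern = activity_pattern,
                 growth_rate_um_per_min = growth_rate_um_per_min,
                 hotspot_amp = hotspot_amp, hotspot_sigma = hotspot_sigma,
                 base_ratio = base_ratio,
                 inhibitor_step = inhibitor_step),
            class = "movie_spec")
}

hotspot_centre <- function(pattern) {
  switch(pattern, distal_hotspot = 5 / 6, central_hotspot = 1 / 2,
         medial_hotspot = 1 / 6, uniform = NA_real_)
}

peak_third_of <- function(pattern) {
  switch(pattern, distal_hotspot = "distal", central_hotspot = "central",
         medial_hotspot = "medial", uniform = NA_character_)
}

# Normalized axis position (0 = medial end, 1 = distal end) of each
# masked pixel of an FA ellipse at the current frame.
axis_positions <- function(spec, fa, centre_px, major_um, mask) {
  scene <- spec$scene
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2L] - centre_px[[1L]]
  y <- -(idx[, 1L] - centre_px[[2L]])      # y up
  th <- fa$orientation_rad
  u <- x * cos(th) + y * sin(th)           # px along major axis
  a <- major_um / 2 / scene$pixel_size_um
  ctr <- scene_centre_px(scene)
  cx <- centre_px[[1L]] - ctr[["x"]]; cy <- -(centre_px[[2L]] - ctr[["y"]])
  # distal end = endpoint farther from the cell centre
  d_plus <- (cx + a * cos(th))^2 + (cy + a * sin(th))^2
  d_minus <- (cx - a * cos(th))^2 + (cy - a * sin(th))^2
  sgn <- if (d_plus >= d_minus) 1 else -1
  s <- (sgn * u + a) / (2 * a)
  list(idx = idx, s = pmin(pmax(s, 0), 1), distal_sign = sgn)
}

#' Render a synthetic two-channel biosensor movie with ground truth
#'
#' @param spec a [movie_spec()].
#' @return List with
#'   \describe{
#'     \item{movie}{an [fa_movie()].}
#'     \item{truth}{data frame, one row per FA per rendered frame:
#'       `frame`, `fa`, `time_s`, `length_um`, centroid (px),
#'       `orientation_rad`, `activity_pattern`, `peak_third`,
#'       `growth_rate_um_per_min`, `growth_class`, `true_mean_ratio`
#'       (planted mean numerator/denominator over the FA).}
#'     \item{truncated}{integer vector: for each FA, the first frame at
#'       which it shrank below one pixel (NA if never).}
#'   }
#' @examples
#' sc <- scene_spec(image_size_px = c(64, 64), cell_radius_um = 4.5,
#'   fa_specs = list(fa_spec(0.6, 0, 2.5, 1)), noise_sigma = 5)
#' mv <- generate_ratio_movie(movie_spec(sc, n_frames = 5,
#'   activity_pattern = "distal_hotspot"))
#' head(mv$truth)
#' @export
generate_ratio_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  scene <- spec$scene
  nr <- scene$image_size_px[1L]; nc <- scene$image_size_px[2L]
  nt <- spec$n_frames
  num <- array(0, c(nr, nc, nt)); den <- array(0, c(nr, nc, nt))
  nfa <- length(scene$fa_specs)
  truncated <- rep(NA_integer_, nfa)
  truth <- list()
  with_seed(scene$seed, {
    for (t in seq_len(nt)) {
      t_min <- (t - 1) * spec$frame_interval_s / 60
      den_sig <- matrix(scene$background_level, nr, nc)
      num_sig <- spec$base_ratio * matrix(scene$background_level, nr, nc)
      inhib <- 1
      if (!is.null(spec$inhibitor_step) &&
          t >= spec$inhibitor_step$frame_on &&
          t < spec$inhibitor_step$frame_off)
        inhib <- 1 - spec$inhibitor_step$ratio_drop
      for (i in seq_len(nfa)) {
        if (!is.na(truncated[i])) next
        fa <- scene$fa_specs[[i]]
        major_t <- fa$major_um + spec$growth_rate_um_per_min[i] * t_min
        if (major_t < scene$pixel_size_um) { truncated[i] <- t; next }
        ctr <- fa_centre_px(scene, fa)
        mask <- render_fa_mask(scene, fa, ctr, major_um = major_t)
        if (!any(mask)) { truncated[i] <- t; next }
        ax <- axis_positions(spec, fa, ctr, major_t, mask)
        act <- rep(1, length(ax$s))
        s0 <- hotspot_centre(spec$activity_pattern[i])
        if (!is.na(s0))
          act <- act + spec$hotspot_amp *
            exp(-(ax$s - s0)^2 / (2 * spec$hotspot_sigma^2))
        act <- act * inhib
        den_sig[ax$idx] <- den_sig[ax$idx] + fa$intensity
        num_sig[ax$idx] <- num_sig[ax$idx] +
          fa$intensity * spec$base_ratio * act
        truth[[length(truth) + 1L]] <- data.frame(
          frame = t, fa = i, time_s = (t - 1) * spec$frame_interval_s,
          length_um = major_t,
          centroid_x_px = ctr[[1L]], centroid_y_px = ctr[[2L]],
          orientation_rad = fa$orientation_rad,
          activity_pattern = spec$activity_pattern[i],
          peak_third = peak_third_of(spec$activity_pattern[i]),
          growth_rate_um_per_min = spec$growth_rate_um_per_min[i],
          growth_class = classify_rate(spec$growth_rate_um_per_min[i]),
          true_mean_ratio = spec$base_ratio * mean(act))
      }
      den_sig <- gaussian_blur(den_sig, scene$psf_sigma_px)
      num_sig <- gaussian_blur(num_sig, scene$psf_sigma_px)
      den[, , t] <- pmax(den_sig +
        matrix(rnorm(nr * nc, 0, scene$noise_sigma), nr, nc), 0)
      num[, , t] <- pmax(num_sig +
        matrix(rnorm(nr * nc, 0, scene$noise_sigma), nr, nc), 0)
    }
  })
  list(movie = fa_movie(num, den, scene$pixel_size_um,
                        spec$frame_interval_s),
       truth = do.call(rbind, truth),
       truncated = truncated)
}

#' Growth-state label for a rate
#'
#' Threshold definition used throughout: `Growing` above +0.02
#' um/min, `Shrinking` below -0.02 um/min, `Stable` between.
#'
#' @param rate_um_per_min numeric vector of rates.
#' @param threshold class boundary in um/min.
#' @return Character vector of `"Growing"`, `"Stable"`, `"Shrinking"`.
#' @export
classify_rate <- function(rate_um_per_min, threshold = 0.02) {
  ifelse(rate_um_per_min > threshold, "Growing",
         ifelse(rate_um_per_min < -threshold, "Shrinking", "Stable"))
}

#' Simulate an FA length trajectory with known class
#'
#' Linear length trend plus i.i.d. Gaussian noise, together with the
#' true growth class implied by the rate.
#'
#' @param rate_um_per_min true linear rate.
#' @param duration_min trajectory duration (>= 5, the persistence
#'   requirement of the growth classifier).
#' @param dt_min sampling interval in minutes (> 0).
#' @param noise_sigma_um standard deviation of length noise.
#' @param seed integer seed.
#' @param length0_um starting length.
#' @return List: `times_min`, `lengths_um`, `true_class`, `rate_um_per_min`.
#' @export
generate_length_trajectory <- function(rate_um_per_min, duration_min,
                                       dt_min, noise_sigma_um = 0,
                                       seed = 1L, length0_um = 2) {
  if (dt_min <= 0) stop("dt_min must be > 0")
  if (duration_min < 5) stop("duration_min must be >= 5")
  if (noise_sigma_um < 0) stop("noise_sigma_um must be >= 0")
  times <- seq(0, duration_min, by = dt_min)
  lengths <- with_seed(seed,
    length0_um + rate_um_per_min * times +
      rnorm(length(times), 0, noise_sigma_um))
  list(times_min = times, lengths_um = lengths,
       true_class = classify_rate(rate_um_per_min),
       rate_um_per_min = rate_um_per_min)
}
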