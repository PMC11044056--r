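#' Simulated study cohorts
#'
#' Cohort-level wrappers around the single-object generators, fixing the
#' study conditions used throughout the package's validation: FA
#' populations with planted sub-FA activity patterns, length-trajectory
#' populations with class-stratified growth rates, and activity-by-state
#' cohorts with a planted ratio offset in stable FAs.
#'
#' `simulate_peak_location_cohort` renders one single-FA biosensor movie
#' per FA (3-s frame interval, the kymograph acquisition regime), runs
#' the full chain — per-frame segmentation, tracking, registration,
#' kymograph, peak scoring — and returns planted versus scored peak
#' thirds.
#'
#' @param n_fas cohort size.
#' @param fractions named fractions of planted `distal`/`central`/
#'   `medial` hot spots (must sum to 1). The default mirrors a
#'   population in which distal peaks dominate and central and medial
#'   peaks occur with lower frequency.
#' @param seed integer seed.
#' @param n_frames frames per movie.
#' @return Data frame: `fa`, `planted`, `scored`.
#' @export
simulate_peak_location_cohort <- function(n_fas = 300L,
                                          fractions = c(distal = 0.6,
                                                        central = 0.25,
                                                        medial = 0.15),
                                          seed = 1L, n_frames = 7L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  counts <- round(n_fas * fractions)
  counts[1L] <- n_fas - sum(counts[-1L])
  patterns <- rep(paste0(names(fractions), "_hotspot"), counts)
  geom <- with_seed(seed, data.frame(
    ang = runif(n_fas, 0, 2 * pi),
    r_rel = runif(n_fas, 0.5, 0.65),
    major = runif(n_fas, 2, 3),
    minor = runif(n_fas, 0.8, 1.1)))
  scored <- character(n_fas)
  ctr <- c((64 + 1) / 2, (64 + 1) / 2)
  params <- segmentation_params(rolling_ball_radius_px = 15,
                                threshold_multiplier_k = 10)
  for (i in seq_len(n_fas)) {
    sc <- scene_spec(image_size_px = c(64L, 64L), pixel_size_um = 0.16,
                     cell_radius_um = 5,
                     fa_specs = list(fa_spec(geom$r_rel[i], geom$ang[i],
                                             geom$major[i], geom$minor[i],
                                             orientation_rad =
                                               atan2(cos(geom$ang[i]),
                                                     sin(geom$ang[i])))),
                     background_level = 100, noise_sigma = 10,
                     psf_sigma_px = 1, seed = seed + i)
    mv <- generate_ratio_movie(movie_spec(sc, n_frames = n_frames,
                                          frame_interval_s = 3,
                                          activity_pattern = patterns[i]))
    res <- analyze_biosensor_movie(mv$movie, params)
    main <- which.max(vapply(res$tracks, nrow, 0L))
    al <- register_fa_patch(mv$movie, res$tracks[[main]], ctr,
                            background_radius = 15)
    scored[i] <- score_peak_location(build_kymograph(al))$third
  }
  data.frame(fa = seq_len(n_fas),
             planted = sub("_hotspot", "", patterns), scored = scored)
}

#' @rdname simulate_peak_location_cohort
#' @param n_trajectories trajectories per cohort.
#' @param noise_sigma_um length noise.
#' @param duration_min,dt_min trajectory sampling (3 frames/min over
#'   10 min by default).
#' @details `simulate_growth_cohort` draws equal thirds of growing,
#'   stable and shrinking FAs with rates sampled away from the decision
#'   boundary (Growing U(0.03, 0.10), Stable U(-0.01, 0.01), Shrinking
#'   U(-0.10, -0.03) um/min), as the three behaviours form distinct
#'   phenotypes in peripheral FAs.
#' @return For `simulate_growth_cohort`: data frame `rate_um_per_min`,
#'   `true_class`, `called_class`.
#' @export
simulate_growth_cohort <- function(n_trajectories = 300L,
                                   noise_sigma_um = 0.05,
                                   duration_min = 10, dt_min = 1 / 3,
                                   seed = 1L) {
  n3 <- n_trajectories %/% 3L
  rates <- with_seed(seed, c(runif(n3, 0.03, 0.10),
                             runif(n3, -0.01, 0.01),
                             runif(n_trajectories - 2L * n3, -0.10, -0.03)))
  out <- data.frame(rate_um_per_min = rates,
                    true_class = classify_rate(rates),
                    called_class = NA_character_)
  for (i in seq_len(n_trajectories)) {
    tr <- generate_length_trajectory(rates[i], duration_min, dt_min,
                                     noise_sigma_um, seed = seed + i)
    out$called_class[i] <- classify_length_series(tr$times_min,
                                                  tr$lengths_um)
  }
  out
}

#' @rdname simulate_peak_location_cohort
#' @param n_per_state cohort sizes for Growing/Stable/Shrinking.
#' @param stable_offset planted additive ratio offset in stable FAs.
#' @param ratio_noise_sd per-frame ratio noise.
#' @details `simulate_state_activity_cohort` builds ratio series and
#'   growth states directly (one segment per FA) with a planted additive
#'   ratio offset in the stable class, for validating the
#'   activity-by-state comparison.
#' @return For `simulate_state_activity_cohort`: list `series`,
#'   `states` (inputs for [summarize_activity_by_state()]) and `classes`.
#' @export
simulate_state_activity_cohort <- function(n_per_state = c(Growing = 30L,
                                                           Stable = 30L,
                                                           Shrinking = 25L),
                                           stable_offset = 0.2,
                                           ratio_noise_sd = 0.05,
                                           duration_min = 10,
                                           dt_min = 1 / 3, seed = 1L) {
  classes <- rep(names(n_per_state), n_per_state)
  n <- length(classes)
  with_seed(seed, {
    rates <- numeric(n)
    rates[classes == "Growing"] <- runif(sum(classes == "Growing"),
                                         0.03, 0.10)
    rates[classes == "Stable"] <- runif(sum(classes == "Stable"),
                                        -0.01, 0.01)
    rates[classes == "Shrinking"] <- runif(sum(classes == "Shrinking"),
                                           -0.10, -0.03)
    tvec <- seq(0, duration_min, by = dt_min)
    series <- vector("list", n); states <- vector("list", n)
    for (i in seq_len(n)) {
      ratio <- 1 + (classes[i] == "Stable") * stable_offset +
        rnorm(length(tvec), 0, ratio_noise_sd)
      series[[i]] <- structure(list(track_id = i, times_s = tvec * 60,
                                    raw_ratio = ratio,
                                    smoothed_ratio = boxcar_smooth(ratio),
                                    frames = seq_along(tvec),
                                    interpolated = rep(FALSE,
                                                       length(tvec))),
                               class = "ratio_series")
      states[[i]] <- structure(list(
        segments = data.frame(t_start = 0, t_end = duration_min,
                              rate_um_per_min = rates[i],
                              class = classes[i]),
        frame_class = rep(classes[i], length(tvec)),
        times_min = tvec), class = "growth_state")
    }
    list(series = series, states = states, classes = classes)
  })
}
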