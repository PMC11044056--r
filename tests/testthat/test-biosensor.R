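make_frame_tables <- function(positions, labels = NULL) {
  # positions: list of matrices (n_fa x 2) of (x, y) um per frame
  lapply(positions, function(p) {
    if (is.null(p) || nrow(p) == 0)
      return(data.frame(label = integer(), centroid_x_um = numeric(),
                        centroid_y_um = numeric(), major_um = numeric(),
                        minor_um = numeric(), orientation_rad = numeric()))
    data.frame(label = seq_len(nrow(p)), centroid_x_um = p[, 1],
               centroid_y_um = p[, 2], major_um = 2, minor_um = 1,
               orientation_rad = 0)
  })
}

test_that("tracking links static FAs, bridges gaps and respects the gate", {
  # two static FAs across 5 frames: two full tracks
  pos <- replicate(5, rbind(c(2, 2), c(8, 8)), simplify = FALSE)
  tracks <- track_fas(make_frame_tables(pos))
  expect_length(tracks, 2L)
  expect_true(all(vapply(tracks, nrow, 0L) == 5L))

  # FA missing for one frame: single track with an interpolated row
  pos_gap <- list(rbind(c(2, 2)), rbind(c(2.1, 2)), NULL,
                  rbind(c(2.3, 2)), rbind(c(2.4, 2)))
  tg <- track_fas(make_frame_tables(pos_gap))
  expect_length(tg, 1L)
  expect_equal(nrow(tg[[1]]), 5L)
  expect_true(tg[[1]]$interpolated[3])
  expect_equal(tg[[1]]$centroid_x_um[3], (2.1 + 2.3) / 2)

  # displacements beyond the gate: tracks terminate rather than jump
  pos_jump <- list(rbind(c(0, 0), c(1.5, 0)), rbind(c(5, 0), c(6.5, 0)))
  ts <- track_fas(make_frame_tables(pos_jump), max_disp_um = 1,
                  bridge_gaps = FALSE)
  expect_length(ts, 4L)
  expect_true(all(vapply(ts, nrow, 0L) == 1L))
  # within the gate the same geometry links into two moving tracks
  pos_ok <- list(rbind(c(0, 0), c(5, 0)), rbind(c(0.8, 0), c(5.8, 0)))
  expect_length(track_fas(make_frame_tables(pos_ok)), 2L)
})

test_that("boxcar smoothing matches hand arithmetic", {
  expect_equal(boxcar_smooth(c(1, 2, 3)), c(1.5, 2, 2.5))
  expect_equal(boxcar_smooth(rep(4, 6)), rep(4, 6))
  expect_equal(boxcar_smooth(c(0, 0, 3, 0, 0)), c(0, 1, 1, 1, 0))
  expect_equal(boxcar_smooth(7), 7)
  # smoothed values stay within the raw window range
  set.seed(2)
  x <- runif(50)
  s <- boxcar_smooth(x)
  for (i in seq_along(x)) {
    w <- x[max(1, i - 1):min(50, i + 1)]
    expect_true(s[i] >= min(w) - 1e-12 && s[i] <= max(w) + 1e-12)
  }
})

test_that("ratio series recover planted ratios and are gain-invariant", {
  sc <- single_fa_scene(13, noise = 5)
  mv <- generate_ratio_movie(movie_spec(sc, n_frames = 6, base_ratio = 2))
  res <- analyze_biosensor_movie(mv$movie, movie_seg_params())
  expect_length(res$tracks, 1L)
  rs <- res$series_objects[[1]]
  expect_true(all(abs(rs$raw_ratio - 2) < 0.1))

  # multiplying both channels by one gain leaves the series unchanged
  mv2 <- mv$movie
  mv2$numerator <- mv2$numerator * 3.7
  mv2$denominator <- mv2$denominator * 3.7
  res2 <- analyze_biosensor_movie(mv2, movie_seg_params())
  expect_equal(res2$series_objects[[1]]$raw_ratio, rs$raw_ratio,
               tolerance = 1e-9)
})

test_that("planted inhibitor steps are recovered from rendered movies", {
  sc <- single_fa_scene(23, noise = 5)
  mv <- generate_ratio_movie(movie_spec(sc, n_frames = 12,
    inhibitor_step = list(frame_on = 7, frame_off = 13, ratio_drop = 0.5)))
  res <- analyze_biosensor_movie(mv$movie, movie_seg_params())
  rs <- res$series_objects[[1]]
  pre <- mean(rs$raw_ratio[1:6], na.rm = TRUE)
  during <- mean(rs$raw_ratio[7:12], na.rm = TRUE)
  expect_close(during / pre, 0.5, 0.05 * 0.5)
})

test_that("registration points the distal end up and kymographs read it out", {
  sc <- single_fa_scene(31, noise = 5)
  mv <- generate_ratio_movie(movie_spec(sc, n_frames = 6,
                                        frame_interval_s = 3,
                                        activity_pattern = "distal_hotspot"))
  res <- analyze_biosensor_movie(mv$movie, movie_seg_params())
  tr <- res$tracks[[1]]
  ctr <- c((64 + 1) / 2, (64 + 1) / 2)
  al <- register_fa_patch(mv$movie, tr, ctr, background_radius = 15)
  # hotspot in the top (distal) third of every patch
  for (p in al$patches) {
    peak <- which(p == max(p, na.rm = TRUE), arr.ind = TRUE)[1, 1]
    expect_lt(peak, nrow(p) / 3 + 2)
  }
  ky <- build_kymograph(al)
  # row-argmax in the distal third at every frame
  for (t in seq_len(ncol(ky$ratio))) {
    j <- which.max(ky$ratio[, t])
    expect_gt(ky$positions[j], 2 / 3)
  }
  expect_equal(score_peak_location(ky)$third, "distal")

  # uniform activity: kymograph flat, mean matches the FA-mean ratio
  mvu <- generate_ratio_movie(movie_spec(sc, n_frames = 6,
                                         frame_interval_s = 3))
  resu <- analyze_biosensor_movie(mvu$movie, movie_seg_params())
  alu <- register_fa_patch(mvu$movie, resu$tracks[[1]], ctr,
                           background_radius = 15)
  kyu <- build_kymograph(alu)
  rng <- range(kyu$ratio, na.rm = TRUE)
  expect_lt(rng[2] - rng[1], 0.25)
  rsu <- resu$series_objects[[1]]
  for (t in seq_len(ncol(kyu$ratio)))
    expect_close(mean(kyu$ratio[, t], na.rm = TRUE), rsu$raw_ratio[t],
                 0.05 * rsu$raw_ratio[t])
})

test_that("peak scoring matches a brute-force argmax and breaks ties as documented", {
  set.seed(8)
  for (rep in 1:20) {
    m <- matrix(runif(25 * 6), 25, 6)
    kym <- structure(list(ratio = m, positions = seq(0, 1, length.out = 25),
                          times_s = seq_len(6)), class = "kymograph")
    sp <- score_peak_location(kym)
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    p <- kym$positions[idx[1]]
    expected <- if (p < 1 / 3) "medial" else if (p < 2 / 3) "central" else
      "distal"
    expect_equal(sp$third, expected)
    expect_false(sp$tie)
  }
  # tie in different thirds: earliest time wins, then larger position
  m <- matrix(0, 9, 4)
  m[2, 3] <- 5; m[8, 2] <- 5
  kym <- structure(list(ratio = m, positions = seq(0, 1, length.out = 9),
                        times_s = 1:4), class = "kymograph")
  sp <- score_peak_location(kym)
  expect_true(sp$tie)
  expect_equal(sp$third, "distal")   # the earlier-time maximum
})

test_that("growth classification follows the rate thresholds and persistence", {
  # constant rates
  for (cfg in list(list(0.05, "Growing"), list(0, "Stable"),
                   list(-0.05, "Shrinking"))) {
    tr <- generate_length_trajectory(cfg[[1]], 10, 1 / 3, 0)
    gs <- classify_growth(tr$times_min, tr$lengths_um)
    expect_equal(nrow(gs$segments), 1L)
    expect_equal(gs$segments$class, cfg[[2]])
    expect_equal(gs$segments$t_start, 0)
    expect_equal(gs$segments$t_end, 10)
  }
  # piecewise: 6 min growth then 6 min shrinkage -> exactly one of each
  t <- seq(0, 12, by = 1 / 3)
  len <- ifelse(t <= 6, 2 + 0.05 * t, 2 + 0.3 - 0.05 * (t - 6))
  gs <- classify_growth(t, len)
  expect_equal(gs$segments$class, c("Growing", "Shrinking"))
  # short track: no classification
  gs0 <- classify_growth(seq(0, 3, by = 1 / 3), rep(2, 10))
  expect_equal(nrow(gs0$segments), 0L)
})

test_that("noise-free classification is exact; noisy accuracy stays high", {
  set.seed(19)
  rates <- c(runif(20, 0.021, 0.1), runif(20, -0.019, 0.019),
             runif(20, -0.1, -0.021))
  for (i in seq_along(rates)) {
    tr <- generate_length_trajectory(rates[i], 10, 1 / 3, 0, seed = i)
    expect_equal(classify_length_series(tr$times_min, tr$lengths_um),
                 tr$true_class)
    gs <- classify_growth(tr$times_min, tr$lengths_um)
    expect_true(all(gs$segments$class == tr$true_class))
  }
})

test_that("state summaries detect planted activity differences", {
  # cohort mirroring the 30/30/25 design: stable FAs carry a +0.2 offset
  set.seed(4)
  classes <- c(rep("Growing", 30), rep("Stable", 30), rep("Shrinking", 25))
  rates <- c(runif(30, 0.03, 0.1), runif(30, -0.01, 0.01),
             runif(25, -0.1, -0.03))
  series <- list(); states <- list()
  for (i in seq_along(classes)) {
    tvec <- seq(0, 10, by = 1 / 3)
    ratio <- 1 + (classes[i] == "Stable") * 0.2 + rnorm(length(tvec), 0, 0.05)
    series[[i]] <- structure(list(track_id = i, times_s = tvec * 60,
                                  raw_ratio = ratio,
                                  smoothed_ratio = boxcar_smooth(ratio),
                                  interpolated = rep(FALSE, length(tvec))),
                             class = "ratio_series")
    states[[i]] <- structure(list(segments = data.frame(
      t_start = 0, t_end = 10, rate_um_per_min = rates[i],
      class = classes[i]), frame_class = rep(classes[i], length(tvec)),
      times_min = tvec), class = "growth_state")
  }
  summ <- summarize_activity_by_state(series, states)
  expect_equal(nrow(summ$per_segment), 85L)
  means <- tapply(summ$per_segment$mean, summ$per_segment$class, mean)
  expect_gt(means["Stable"], means["Growing"])
  expect_gt(means["Stable"], means["Shrinking"])
  expect_lt(summ$anova$mean$p_value, 0.05)

  # identical ratios everywhere: ANOVA finds nothing
  series_flat <- lapply(series, function(s) {
    s$raw_ratio[] <- 1; s$smoothed_ratio[] <- 1; s
  })
  summ_flat <- summarize_activity_by_state(series_flat, states)
  expect_true(is.na(summ_flat$anova$mean$p_value) ||
                summ_flat$anova$mean$p_value > 0.9)

  # planted linear max-ratio ~ rate in growing FAs is recovered
  set.seed(9)
  series_lin <- series
  for (i in which(classes == "Growing")) {
    tvec <- seq(0, 10, by = 1 / 3)
    ratio <- 1 + 5 * abs(rates[i]) + rnorm(length(tvec), 0, 0.02)
    series_lin[[i]]$raw_ratio <- ratio
    series_lin[[i]]$smoothed_ratio <- boxcar_smooth(ratio)
  }
  summ_lin <- summarize_activity_by_state(series_lin, states)
  gr <- summ_lin$correlations
  gr <- gr[gr$class == "Growing" & gr$statistic == "max", ]
  expect_gt(gr$slope, 0)
  expect_gt(gr$r_squared, 0.8)
  expect_lt(gr$p_value, 0.05)
})
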