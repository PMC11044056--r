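ls_slope <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2L) return(NA_real_)
  tc <- t - mean(t)
  s2 <- sum(tc^2)
  if (s2 == 0) return(NA_real_)
  sum(tc * (y - mean(y))) / s2
}

#' Classify FA growth state from a length time series
#'
#' Rates are least-squares slopes of length versus time over a sliding
#' 5-min window stepped one frame at a time. Each window is labelled
#' `Growing` (> +0.02 um/min), `Shrinking` (< -0.02) or `Stable`; each
#' frame takes the majority label of the windows covering it (ties go to
#' `Stable`); maximal runs of identically labelled frames spanning at
#' least 5 min become segments. A track that grows and then shrinks
#' contributes one segment per behaviour, so one FA can appear in
#' several state cohorts.
#'
#' @param times_min sample times in minutes (strictly increasing).
#' @param lengths_um FA lengths in micrometres; or pass an `fa_track`
#'   plus `frame_interval_s` via [classify_growth_track()].
#' @param window_min window and minimum persistence, minutes.
#' @param threshold rate threshold in um/min.
#' @return A `growth_state` object: `segments` data frame (`t_start`,
#'   `t_end` in minutes, `rate_um_per_min`, `class`), `frame_class`,
#'   `times_min`. Tracks shorter than `window_min` yield no segments.
#' @examples
#' tr <- generate_length_trajectory(0.05, 10, 1/3, 0, seed = 1)
#' classify_growth(tr$times_min, tr$lengths_um)$segments
#' @export
classify_growth <- function(times_min, lengths_um, window_min = 5,
                            threshold = 0.02) {
  stopifnot(length(times_min) == length(lengths_um),
            !is.unsorted(times_min, strictly = TRUE))
  n <- length(times_min)
  span <- times_min[n] - times_min[1L]
  empty <- data.frame(t_start = numeric(), t_end = numeric(),
                      rate_um_per_min = numeric(), class = character())
  if (span < window_min - 1e-9)
    return(structure(list(segments = empty,
                          frame_class = rep(NA_character_, n),
                          times_min = times_min), class = "growth_state"))
  # sliding windows: start at each frame whose 5-min window fits
  votes <- matrix(0L, n, 3L, dimnames = list(NULL, c("Growing", "Stable",
                                                     "Shrinking")))
  for (i in seq_len(n)) {
    if (times_min[i] + window_min > times_min[n] + 1e-9) break
    j <- max(which(times_min <= times_min[i] + window_min + 1e-9))
    rate <- ls_slope(times_min[i:j], lengths_um[i:j])
    if (is.na(rate)) next
    cls <- classify_rate(rate, threshold)
    votes[i:j, cls] <- votes[i:j, cls] + 1L
  }
  frame_class <- apply(votes, 1L, function(v) {
    if (sum(v) == 0L) return(NA_character_)
    top <- which(v == max(v))
    if (length(top) > 1L) "Stable" else colnames(votes)[top]
  })
  # maximal runs of identical class spanning >= window_min
  segs <- list()
  r <- rle(frame_class)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (is.na(r$values[k])) next
    i0 <- starts[k]; i1 <- ends[k]
    if (times_min[i1] - times_min[i0] < window_min - 1e-9) next
    segs[[length(segs) + 1L]] <- data.frame(
      t_start = times_min[i0], t_end = times_min[i1],
      rate_um_per_min = ls_slope(times_min[i0:i1], lengths_um[i0:i1]),
      class = r$values[k])
  }
  structure(list(segments = if (length(segs)) do.call(rbind, segs) else
                   empty,
                 frame_class = frame_class, times_min = times_min),
            class = "growth_state")
}

#' @rdname classify_growth
#' @param track an `fa_track` from [track_fas()].
#' @param frame_interval_s movie frame interval in seconds.
#' @export
classify_growth_track <- function(track, frame_interval_s,
                                  window_min = 5, threshold = 0.02) {
  classify_growth((track$frame - 1) * frame_interval_s / 60,
                  track$length_um, window_min, threshold)
}

#' @export
print.growth_state <- function(x, ...) {
  if (nrow(x$segments) == 0L) {
    cat("growth_state: no segments (track shorter than the window)\n")
  } else {
    cat("growth_state segments:\n")
    print(x$segments, row.names = FALSE)
  }
  invisible(x)
}

#' Single growth label for a whole trajectory
#'
#' Convenience classifier for trajectories that exhibit one behaviour:
#' the least-squares slope over the full track, thresholded at
#' +/-0.02 um/min.
#'
#' @param times_min,lengths_um length time series.
#' @param threshold rate threshold in um/min.
#' @return `"Growing"`, `"Stable"` or `"Shrinking"`.
#' @export
classify_length_series <- function(times_min, lengths_um,
                                   threshold = 0.02) {
  classify_rate(ls_slope(times_min, lengths_um), threshold)
}

#' Summarize biosensor activity by growth state across a cohort
#'
#' For every growth segment of every FA, the minimum, mean and maximum
#' of the smoothed biosensor ratio within the segment are collected.
#' States are compared per statistic by one-way ANOVA with Tukey HSD
#' multiple comparisons, and within each state each statistic is
#' regressed on the growth-rate magnitude (ordinary least squares,
#' two-sided p), mirroring the standard ratio-versus-rate scatter
#' analysis.
#'
#' @param series_list list of `ratio_series` (one per FA).
#' @param states_list list of `growth_state` (same order).
#' @param use_smoothed use the boxcar-smoothed ratio (default) or raw.
#' @return An `activity_summary` object: `per_segment` data frame
#'   (`fa`, `class`, `rate_um_per_min`, `min`, `mean`, `max`), `anova`
#'   (per-statistic p-values and Tukey HSD tables), `correlations`
#'   (per state x statistic: `slope`, `r_squared`, `p_value`, `n`).
#' @export
summarize_activity_by_state <- function(series_list, states_list,
                                        use_smoothed = TRUE) {
  stopifnot(length(series_list) == length(states_list))
  rows <- list()
  for (i in seq_along(series_list)) {
    rs <- series_list[[i]]; gs <- states_list[[i]]
    if (nrow(gs$segments) == 0L) next
    t_min <- rs$times_s / 60
    vals_all <- if (use_smoothed) rs$smoothed_ratio else rs$raw_ratio
    for (k in seq_len(nrow(gs$segments))) {
      seg <- gs$segments[k, ]
      sel <- t_min >= seg$t_start - 1e-9 & t_min <= seg$t_end + 1e-9
      v <- vals_all[sel]; v <- v[is.finite(v)]   # gaps excluded, not imputed
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        fa = i, class = seg$class, rate_um_per_min = seg$rate_um_per_min,
        min = min(v), mean = mean(v), max = max(v))
    }
  }
  per_segment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fa = integer(), class = character(),
               rate_um_per_min = numeric(), min = numeric(),
               mean = numeric(), max = numeric())
  anova_res <- list(); cor_res <- list()
  if (nrow(per_segment) && length(unique(per_segment$class)) >= 2L) {
    for (stat in c("min", "mean", "max")) {
      if (stats::var(per_segment[[stat]]) < 1e-18) {
        # degenerate constant data: no evidence of any difference
        anova_res[[stat]] <- list(p_value = 1, tukey = NULL)
        next
      }
      fit <- aov(per_segment[[stat]] ~ factor(per_segment$class))
      p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      anova_res[[stat]] <- list(p_value = p,
                                tukey = TukeyHSD(fit)[[1L]])
    }
  }
  for (cls in unique(per_segment$class)) {
    sub <- per_segment[per_segment$class == cls, ]
    for (stat in c("min", "mean", "max")) {
      n_ok <- sum(is.finite(sub[[stat]]) & is.finite(sub$rate_um_per_min))
      if (n_ok < 3L) next   # regression undefined below 3 points
      if (stats::var(sub[[stat]]) < 1e-18) next   # constant response
      fit <- lm(sub[[stat]] ~ abs(sub$rate_um_per_min))
      sm <- summary(fit)
      cor_res[[paste(cls, stat, sep = ".")]] <- data.frame(
        class = cls, statistic = stat,
        slope = unname(coef(fit)[2L]),
        r_squared = sm$r.squared,
        p_value = sm$coefficients[2L, 4L], n = n_ok)
    }
  }
  structure(list(per_segment = per_segment, anova = anova_res,
                 correlations = if (length(cor_res))
                   do.call(rbind, c(cor_res, make.row.names = FALSE)) else
                   NULL),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat("Activity by growth state\n")
  if (nrow(x$per_segment)) {
    agg <- aggregate(cbind(min, mean, max) ~ class, x$per_segment, mean)
    cat("  per-state mean of segment statistics:\n")
    print(agg, row.names = FALSE)
    for (stat in names(x$anova))
      cat(sprintf("  ANOVA (%s): p = %.4g\n", stat,
                  x$anova[[stat]]$p_value))
    if (!is.null(x$correlations)) {
      cat("  ratio-vs-|rate| regressions:\n")
      print(x$correlations, row.names = FALSE, digits = 3)
    }
  } else cat("  (no segments)\n")
  invisible(x)
}
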