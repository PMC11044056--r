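# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# sup_x |ECDF1(x) - ECDF2(x)| by scanning every sample point
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), 0))
}

# naive double-loop Pearson correlation over a raster pair
pearson_oracle <- function(A, B) {
  n <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    n <- n + 1; sa <- sa + A[i, j]; sb <- sb + B[i, j]
  }
  ma <- sa / n; mb <- sb / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    num <- num + (A[i, j] - ma) * (B[i, j] - mb)
    da <- da + (A[i, j] - ma)^2
    db <- db + (B[i, j] - mb)^2
  }
  num / sqrt(da * db)
}

icq_oracle <- function(A, B) {
  ma <- mean(A); mb <- mean(B)
  npos <- 0; n <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    n <- n + 1
    if ((A[i, j] - ma) * (B[i, j] - mb) > 0) npos <- npos + 1
  }
  npos / n - 0.5
}

manders_oracle <- function(A, B, thrA, thrB) {
  nA <- 0; nB <- 0; nAB <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    a <- A[i, j] > thrA; b <- B[i, j] > thrB
    if (a) nA <- nA + 1
    if (b) nB <- nB + 1
    if (a && b) nAB <- nAB + 1
  }
  c(m1 = nAB / nA, m2 = nAB / nB)
}

# per-protein re-evaluation of the N-of-M hit rule
hit_oracle <- function(enrichments, threshold, min_trials) {
  passing <- 0L
  for (e in enrichments) {
    if (is.na(e)) next
    if (is.infinite(e) || e >= threshold) passing <- passing + 1L
  }
  passing >= min_trials
}

# a tiny single-FA scene for movie tests: FA at angle `ang`, radially
# oriented, in a 64x64 cell
single_fa_scene <- function(seed, ang = 0.8, r_rel = 0.6, major = 2.5,
                            minor = 1, noise = 10, intensity = 400) {
  scene_spec(image_size_px = c(64L, 64L), pixel_size_um = 0.16,
             cell_radius_um = 4.8,
             fa_specs = list(fa_spec(r_rel, ang, major, minor,
                                     orientation_rad = atan2(cos(ang),
                                                             sin(ang)),
                                     intensity = intensity)),
             background_level = 100, noise_sigma = noise,
             psf_sigma_px = 1, seed = seed)
}

# segmentation tuned to the small 64x64 movie scenes
movie_seg_params <- function() segmentation_params(rolling_ball_radius_px = 15)

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
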