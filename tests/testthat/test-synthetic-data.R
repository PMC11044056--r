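test_that("scene rendering honours geometry, seeds and overlap rules", {
  # empty scene: background plus noise only, empty truth
  blank <- generate_cell_image(scene_spec(image_size_px = c(32L, 32L),
                                          cell_radius_um = 2,
                                          noise_sigma = 5, seed = 2))
  expect_equal(nrow(blank$truth), 0L)
  expect_equal(dim(blank$channels$fa), c(32L, 32L))

  # analytic ellipse area: major 2 x minor 1 um -> pi * 1 * 0.5
  sc <- scene_spec(fa_specs = list(fa_spec(0.5, 1, 2, 1)), seed = 1)
  img <- generate_cell_image(sc)
  expect_equal(img$truth$area_um2, pi * 1 * 0.5, tolerance = 1e-12)

  # same spec, different seeds: identical truth, different noise
  sc2 <- sc; sc2$seed <- 99L
  img2 <- generate_cell_image(sc2)
  expect_equal(img$truth, img2$truth)
  expect_gt(max(abs(frame_matrix(img$channels$fa) -
                      frame_matrix(img2$channels$fa))), 0)

  # identical spec + seed: bit-identical output
  img3 <- generate_cell_image(sc)
  expect_identical(frame_matrix(img$channels$fa),
                   frame_matrix(img3$channels$fa))

  # overlapping FAs are an ambiguity error
  bad <- scene_spec(fa_specs = list(fa_spec(0.5, 1, 2, 1),
                                    fa_spec(0.5, 1.02, 2, 1)))
  expect_error(generate_cell_image(bad), "overlap")

  # FA protruding past the cell boundary is rejected at spec time
  expect_error(scene_spec(cell_radius_um = 5,
                          fa_specs = list(fa_spec(0.9, 0, 4, 1))),
               "fit")
})

test_that("noise-free, blur-free rendering recovers planted area to pixel quantization", {
  sc <- scene_spec(fa_specs = list(fa_spec(0.4, 2, 3, 1.2)),
                   noise_sigma = 0, psf_sigma_px = 0, seed = 7)
  img <- generate_cell_image(sc)
  m <- frame_matrix(img$channels$fa)
  npx <- sum(m > sc$background_level)
  px_area <- sc$pixel_size_um^2
  # one pixel-quantization bound: perimeter x pixel size
  perim_um <- pi * (3 + 1.2) / 2
  expect_lt(abs(npx * px_area - img$truth$area_um2),
            perim_um * sc$pixel_size_um + px_area)
})

test_that("ratio movies plant the advertised activity patterns", {
  sc <- single_fa_scene(5, noise = 0)
  # uniform, no growth, no step: constant true ratio over time
  mv <- generate_ratio_movie(movie_spec(sc, n_frames = 5))
  expect_equal(unique(mv$truth$true_mean_ratio), 1)
  expect_equal(unique(mv$truth$length_um), 2.5)

  # distal hotspot raises the mean ratio and labels the distal third
  mvd <- generate_ratio_movie(movie_spec(sc, n_frames = 5,
                                         activity_pattern = "distal_hotspot"))
  expect_true(all(mvd$truth$peak_third == "distal"))
  expect_true(all(mvd$truth$true_mean_ratio > 1))

  # inhibitor step: mean true ratio during the step is (1 - drop) x before
  mvs <- generate_ratio_movie(movie_spec(sc, n_frames = 8,
    inhibitor_step = list(frame_on = 5, frame_off = 9, ratio_drop = 0.5)))
  pre <- mean(mvs$truth$true_mean_ratio[mvs$truth$frame < 5])
  during <- mean(mvs$truth$true_mean_ratio[mvs$truth$frame >= 5])
  expect_equal(during, 0.5 * pre, tolerance = 1e-12)

  # growth changes length linearly; shrink-below-a-pixel truncates
  mvg <- generate_ratio_movie(movie_spec(sc, n_frames = 5,
                                         frame_interval_s = 60,
                                         growth_rate_um_per_min = 0.1))
  expect_equal(mvg$truth$length_um, 2.5 + 0.1 * (mvg$truth$frame - 1),
               tolerance = 1e-9)
  mvt <- generate_ratio_movie(movie_spec(sc, n_frames = 10,
                                         frame_interval_s = 60,
                                         growth_rate_um_per_min = -0.5))
  expect_false(is.na(mvt$truncated[1]))
  expect_lt(max(mvt$truth$frame), 10)
})

test_that("length trajectories carry the threshold-defined class", {
  expect_equal(generate_length_trajectory(0.05, 10, 1/3, 0)$true_class,
               "Growing")
  expect_equal(generate_length_trajectory(0, 10, 1/3, 0)$true_class,
               "Stable")
  expect_equal(generate_length_trajectory(-0.05, 10, 1/3, 0)$true_class,
               "Shrinking")
  expect_error(generate_length_trajectory(0.05, 10, 0, 0), "dt_min")
  expect_error(generate_length_trajectory(0.05, 3, 1/3, 0), "duration")
  # noise-free trajectory is exactly linear
  tr <- generate_length_trajectory(0.04, 8, 0.5, 0, length0_um = 1.5)
  expect_equal(tr$lengths_um, 1.5 + 0.04 * tr$times_min)
})

test_that("quant tables embed exact folds, missingness and planted sets", {
  # no hits -> empty truth
  g0 <- generate_quant_table(quant_table_spec(n_proteins = 10,
    n_planted_hits = 0, missingness_rate = 0, seed = 4))
  expect_length(g0$true_hits, 0)

  # noise-free: enrichment exactly planted_fold for hits, 1.0 otherwise
  g <- generate_quant_table(quant_table_spec(n_proteins = 40,
    n_planted_hits = 5, planted_fold = 8, lognormal_noise_sigma = 0,
    missingness_rate = 0, control_enriched_fraction = 0, seed = 4))
  enr <- compute_enrichment(g$table)
  em <- as.matrix(enr[, paste0("enrichment.", 1:4)])
  hits <- enr$accession %in% g$true_hits
  expect_true(all(em[hits, ] == 8))
  expect_true(all(em[!hits, ] == 1))

  # missingness produces about the requested fraction of zero entries
  gm <- generate_quant_table(quant_table_spec(n_proteins = 1000,
    missingness_rate = 0.1, seed = 9))
  im <- as.matrix(gm$table[, -(1:2)])
  frac <- mean(im == 0)
  expect_close(frac, 0.1, 3 * sqrt(0.1 * 0.9 / length(im)) + 0.005)

  # determinism
  g2 <- generate_quant_table(quant_table_spec(n_proteins = 40,
    n_planted_hits = 5, planted_fold = 8, lognormal_noise_sigma = 0,
    missingness_rate = 0, control_enriched_fraction = 0, seed = 4))
  expect_identical(g$table, g2$table)
})
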