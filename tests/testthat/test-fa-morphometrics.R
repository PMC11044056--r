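test_that("shape descriptors match closed-form geometry", {
  # 4x4 square at 0.1 um/px: area 0.16, aspect exactly 1
  sq <- as.matrix(expand.grid(row = 3:6, col = 11:14))
  d <- compute_shape_descriptors(sq, 0.1)
  expect_equal(d$area_um2, 0.16)
  expect_equal(d$aspect_ratio, 1)

  # 20x5 rectangle: aspect 4 within the moment-estimator tolerance
  rect <- as.matrix(expand.grid(row = 1:5, col = 1:20))
  d2 <- compute_shape_descriptors(rect, 0.1)
  expect_close(d2$aspect_ratio, 4, 0.2)
  expect_equal(d2$orientation_rad, 0)   # long axis along x

  # single pixel: defined, aspect 1
  d3 <- compute_shape_descriptors(cbind(5, 5), 0.1)
  expect_equal(d3$aspect_ratio, 1)

  # 90-degree rotation: same area and aspect, orientation shifted
  rect_rot <- rect[, c(2, 1)]
  colnames(rect_rot) <- c("row", "col")
  d4 <- compute_shape_descriptors(rect_rot, 0.1)
  expect_equal(d4$area_um2, d2$area_um2)
  expect_equal(d4$aspect_ratio, d2$aspect_ratio)
  expect_equal(abs(d4$orientation_rad - d2$orientation_rad), pi / 2)

  expect_error(compute_shape_descriptors(matrix(0, 0, 2), 0.1), "empty")
})

test_that("segmentation recovers planted scenes and validates parameters", {
  # blank image: empty result, not an error
  blank <- image_frame(matrix(0, 32, 32), 0.16)
  expect_equal(nrow(segment_fas(blank)$fas), 0L)

  # out-of-range threshold multiplier
  expect_error(segmentation_params(threshold_multiplier_k = 20), "9")
  expect_error(segmentation_params(threshold_multiplier_k = 8.5), "9")

  # planted scene at default noise: all FAs found, areas near truth
  sc <- random_scene_spec(n_fas = 10, seed = 42)
  img <- generate_cell_image(sc)
  seg <- segment_fas(img$channels$fa)
  expect_equal(nrow(seg$fas), 10L)
  expect_true(seg$k >= 9 && seg$k <= 15)
  for (i in seq_len(10)) {
    d <- sqrt((seg$fas$centroid_x_um - img$truth$centroid_x_um[i])^2 +
                (seg$fas$centroid_y_um - img$truth$centroid_y_um[i])^2)
    j <- which.min(d)
    expect_lt(min(d), 0.5)
    expect_lt(abs(seg$fas$area_um2[j] - img$truth$area_um2[i]) /
                img$truth$area_um2[i], 0.15)
  }
})

test_that("raising the threshold multiplier never grows the segmented area", {
  sc <- random_scene_spec(n_fas = 8, seed = 17)
  img <- generate_cell_image(sc)
  ps <- pixel_size(img$channels$fa)
  areas <- vapply(9:15, function(k) {
    seg <- segment_fas(img$channels$fa,
                       segmentation_params(threshold_multiplier_k = k,
                                           min_area_um2 = 0))
    sum(seg$labels > 0) * ps^2
  }, 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("8-connectivity joins diagonal pixels and splits separated blobs", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1; m[3, 3] <- 1          # diagonal pair: one component
  m[6, 6:7] <- 1                       # separate blob
  lab <- label_components_8(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_false(lab[2, 2] == lab[6, 6])
  # 1-px gap stays split
  m2 <- matrix(0, 5, 5); m2[2, 1:2] <- 1; m2[2, 4:5] <- 1
  expect_equal(max(label_components_8(m2)), 2L)
})

test_that("relative radial distance follows circle geometry", {
  mask <- outer(1:101, 1:101,
                function(r, c) (r - 51)^2 + (c - 51)^2 <= 50^2)
  ctr <- c(51, 51)
  expect_equal(relative_radial_distance(ctr, ctr, mask), 0)
  expect_close(relative_radial_distance(c(76, 51), ctr, mask), 0.5, 0.01)
  expect_close(relative_radial_distance(c(101, 51), ctr, mask), 1, 0.01)
  expect_close(relative_radial_distance(c(51 + 25 / sqrt(2), 51 + 25 / sqrt(2)),
                                        ctr, mask), 0.5, 0.01)
  # clamped at 1 even past the boundary
  expect_equal(relative_radial_distance(c(120, 51), ctr, mask), 1)
})

test_that("planted radial positions are recovered through segmentation", {
  errs <- c()
  for (s in 1:5) {
    sc <- random_scene_spec(n_fas = 8, seed = 100 + s)
    img <- generate_cell_image(sc)
    seg <- segment_fas(img$channels$fa)
    fas <- fa_radial_distances(seg, img$channels$cell, sc$pixel_size_um)
    for (i in seq_len(nrow(img$truth))) {
      d <- sqrt((fas$centroid_x_um - img$truth$centroid_x_um[i])^2 +
                  (fas$centroid_y_um - img$truth$centroid_y_um[i])^2)
      if (length(d) && min(d) < 0.5)
        errs <- c(errs, abs(fas$r_rel[which.min(d)] - img$truth$r_rel[i]))
    }
  }
  expect_gt(length(errs), 30)
  expect_lt(max(errs), 0.05)
})

test_that("polar unwrap linearizes rotationally structured images", {
  n <- 101; ctr <- (n + 1) / 2
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  # constant image stays constant
  un_const <- polar_unwrap(matrix(3, n, n))
  expect_true(all(abs(un_const - 3) < 1e-9, na.rm = TRUE))
  # bright ring at radius 30 -> bright column at radius 30
  ring <- exp(-(r - 30)^2 / 2)
  un <- polar_unwrap(ring, n_angles = 90)
  radial_profile <- colMeans(un, na.rm = TRUE)
  expect_close(attr(un, "radii_px")[which.max(radial_profile)], 30, 1)
  # rotational symmetry: every angular row near-identical
  row_sd <- apply(un, 2, sd, na.rm = TRUE)
  expect_lt(max(row_sd, na.rm = TRUE), 0.05 * max(ring))
})

test_that("KS comparison equals the brute-force ECDF oracle", {
  expect_equal(ks_compare(1:5, 1:5)$ks_distance, 0)
  expect_equal(ks_compare(1:4, 5:8)$ks_distance, 1)
  expect_equal(ks_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))$ks_distance, 0.5)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")

  # exhaustive small samples over a small alphabet
  set.seed(7)
  for (rep in 1:200) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    r <- ks_compare(x, y)
    expect_equal(r$ks_distance, ks_oracle(x, y), tolerance = 1e-12)
    expect_equal(c(r$n1, r$n2), c(n1, n2))
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})
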