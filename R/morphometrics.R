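#' Shape descriptors of a segmented component
#'
#' Computes the morphometric fields of one focal adhesion from its pixel
#' set: area (pixel count times pixel area), centroid, and the
#' ellipse-equivalent axes from second central moments of the pixel
#' coordinates. A discrete-pixel variance correction of 1/12 per
#' coordinate (the variance of a unit pixel) is added before the
#' eigendecomposition, so an n x m axis-aligned rectangle has aspect
#' ratio exactly n/m and a single pixel is well-defined with aspect 1.
#'
#' Orientation is the major-axis angle relative to the +x (column) axis
#' with y measured upwards, in `[-pi/2, pi/2)`.
#'
#' @param pixels two-column matrix of (row, col) indices, as returned by
#'   `which(labels == id, arr.ind = TRUE)`.
#' @param pixel_size_um pixel size in micrometres.
#' @return One-row data frame: `area_um2`, `aspect_ratio`,
#'   `centroid_x_um`, `centroid_y_um`, `orientation_rad`, `major_um`,
#'   `minor_um`.
#' @examples
#' sq <- as.matrix(expand.grid(row = 1:4, col = 1:4))
#' compute_shape_descriptors(sq, 0.1)   # area 0.16 um^2, aspect 1
#' @export
compute_shape_descriptors <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L) stop("empty pixel set")
  stopifnot(ncol(pixels) == 2L, pixel_size_um > 0)
  n <- nrow(pixels)
  x <- pixels[, 2L]          # columns -> x
  y <- -pixels[, 1L]         # rows increase downwards; flip so y is up
  mx <- mean(x); my <- mean(y)
  # population moments + 1/12 pixel-extent correction
  cxx <- mean((x - mx)^2) + 1 / 12
  cyy <- mean((y - my)^2) + 1 / 12
  cxy <- mean((x - mx) * (y - my))
  tr <- cxx + cyy
  disc <- sqrt((cxx - cyy)^2 + 4 * cxy^2)
  l1 <- (tr + disc) / 2
  l2 <- max((tr - disc) / 2, 1e-12)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  data.frame(area_um2 = n * pixel_size_um^2,
             aspect_ratio = sqrt(l1 / l2),
             centroid_x_um = (mx - 0.5) * pixel_size_um,
             centroid_y_um = (-my - 0.5) * pixel_size_um,
             orientation_rad = wrap_orientation(theta),
             major_um = 4 * sqrt(l1) * pixel_size_um,
             minor_um = 4 * sqrt(l2) * pixel_size_um)
}

#' Relative radial distance of an FA centroid
#'
#' Distance of an FA centroid from the cell centroid, normalized by the
#' distance from the cell centroid to the cell boundary along the same
#' ray, so that 0 is the cell centre and 1 the periphery. The boundary
#' is found by marching along the ray through the binary cell mask.
#'
#' @param fa_centroid,cell_centroid numeric pairs `(x, y)` in pixel
#'   units (1-based, continuous; x = column, y = row).
#' @param cell_mask binary matrix; nonzero inside the cell.
#' @param step_px ray-marching step.
#' @return `r_rel` in `[0, 1]`.
#' @examples
#' mask <- outer(1:101, 1:101, function(r, c) (r - 51)^2 + (c - 51)^2 <= 50^2)
#' relative_radial_distance(c(76, 51), c(51, 51), mask)  # 0.5
#' @export
relative_radial_distance <- function(fa_centroid, cell_centroid, cell_mask,
                                     step_px = 0.25) {
  dx <- fa_centroid[[1L]] - cell_centroid[[1L]]
  dy <- fa_centroid[[2L]] - cell_centroid[[2L]]
  d_fa <- sqrt(dx^2 + dy^2)
  if (d_fa < 1e-9) return(0)
  ux <- dx / d_fa; uy <- dy / d_fa
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  inside <- function(t) {
    x <- cell_centroid[[1L]] + t * ux
    y <- cell_centroid[[2L]] + t * uy
    r <- round(y); c <- round(x)
    r >= 1 && r <= nr && c >= 1 && c <= nc && cell_mask[r, c] > 0
  }
  if (!inside(0)) stop("cell_centroid is outside cell_mask")
  t <- 0
  while (inside(t + step_px)) t <- t + step_px
  d_boundary <- t + step_px / 2
  min(max(d_fa / d_boundary, 0), 1)
}

# Rasterize the convex hull of a set of (row, col) pixels into a mask.
convex_hull_mask <- function(pixels, nr, nc) {
  pixels <- as.matrix(pixels)
  h <- grDevices::chull(pixels[, 2L], pixels[, 1L])
  vx <- pixels[h, 2L]; vy <- pixels[h, 1L]
  mask <- matrix(FALSE, nr, nc)
  cx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cy <- matrix(seq_len(nr), nr, nc)
  # even-odd ray casting, vectorized over pixels
  nv <- length(vx); crossings <- matrix(0L, nr, nc)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[j]; y2 <- vy[j]
    if (y1 == y2) next
    cond <- ((cy > pmin(y1, y2)) & (cy <= pmax(y1, y2)))
    xi <- x1 + (cy - y1) * (x2 - x1) / (y2 - y1)
    crossings <- crossings + (cond & (cx <= xi))
  }
  mask[crossings %% 2L == 1L] <- TRUE
  mask
}

#' Radial positions for a table of segmented FAs
#'
#' Computes `r_rel` for every FA in a segmentation result. The cell
#' outline is taken from a whole-cell channel when provided (mask =
#' nonzero pixels, centroid = mask centroid); otherwise the convex hull
#' of all segmented FA pixels stands in for the cell outline.
#'
#' @param seg result of [segment_fas()].
#' @param cell an optional [image_frame()] whole-cell channel (treated
#'   as a binary mask: nonzero = inside).
#' @param pixel_size_um pixel size; required only to keep the centroid
#'   conversion consistent with `seg`.
#' @return `seg$fas` with an `r_rel` column appended.
#' @export
fa_radial_distances <- function(seg, cell = NULL, pixel_size_um) {
  fas <- seg$fas
  if (nrow(fas) == 0L) { fas$r_rel <- numeric(0); return(fas) }
  if (!is.null(cell)) {
    mask <- frame_matrix(cell) > 0
  } else {
    px <- which(seg$labels > 0L, arr.ind = TRUE)
    mask <- convex_hull_mask(px, nrow(seg$labels), ncol(seg$labels))
  }
  idx <- which(mask, arr.ind = TRUE)
  cell_centroid <- c(mean(idx[, 2L]), mean(idx[, 1L]))
  fas$r_rel <- vapply(seq_len(nrow(fas)), function(i) {
    ctr <- c(fas$centroid_x_um[i] / pixel_size_um + 0.5,
             fas$centroid_y_um[i] / pixel_size_um + 0.5)
    relative_radial_distance(ctr, cell_centroid, mask)
  }, 0)
  fas
}

# Bilinear interpolation at continuous (x = col, y = row) positions,
# pixel centres at integer coordinates; NA outside the raster.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  out[ok] <- m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
  out
}

#' Polar unwrap of a cell image
#'
#' Resamples an image into polar coordinates around a centre point: rows
#' sample the angle clockwise from the image "up" direction, columns
#' sample the radius from 0 outward, with bilinear interpolation. This
#' linearizes a round cell so the radial position of FAs can be read
#' along the horizontal axis; it is a visualization aid — quantitative
#' radial statistics come from [relative_radial_distance()].
#'
#' @param image an [image_frame()] or plain matrix.
#' @param center `(x, y)` centre in pixel units; default image centre.
#' @param n_angles number of angular samples (rows of the output).
#' @param n_radii number of radial samples; default one per pixel of
#'   radius.
#' @param max_radius_px outer radius; default the largest radius fully
#'   inside the image.
#' @return Numeric matrix (angle x radius) with attributes `angles_rad`
#'   and `radii_px`.
#' @export
polar_unwrap <- function(image, center = NULL, n_angles = 360L,
                         n_radii = NULL, max_radius_px = NULL) {
  m <- if (inherits(image, "image_frame")) frame_matrix(image) else
    as.matrix(image)
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(center)) center <- c((nc + 1) / 2, (nr + 1) / 2)
  if (center[1L] < 1 || center[1L] > nc || center[2L] < 1 ||
      center[2L] > nr)
    stop("center must lie inside the image")
  if (is.null(max_radius_px))
    max_radius_px <- min(center[1L] - 1, nc - center[1L],
                         center[2L] - 1, nr - center[2L])
  if (is.null(n_radii)) n_radii <- max(2L, ceiling(max_radius_px))
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  radii <- seq(0, max_radius_px, length.out = n_radii)
  # clockwise from "up": angle 0 -> -row direction, pi/2 -> +col
  xs <- outer(sin(angles), radii) + center[1L]
  ys <- outer(-cos(angles), radii) + center[2L]
  out <- matrix(bilinear_sample(m, as.vector(xs), as.vector(ys)),
                n_angles, n_radii)
  attr(out, "angles_rad") <- angles
  attr(out, "radii_px") <- radii
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two empirical distributions (e.g. `r_rel` histograms of FAs
#' from control and treated cells) by the two-sample KS statistic
#' `D = sup |ECDF1 - ECDF2|` with the asymptotic p-value.
#'
#' @param sample1,sample2 non-empty numeric vectors.
#' @return A `ks_comparison` object: `ks_distance`, `p_value`, `n1`, `n2`.
#' @examples
#' ks_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))$ks_distance  # 0.5
#' @export
ks_compare <- function(sample1, sample2) {
  if (length(sample1) == 0L || length(sample2) == 0L)
    stop("both samples must be non-empty")
  st <- suppressWarnings(stats::ks.test(sample1, sample2, exact = FALSE))
  structure(list(ks_distance = unname(st$statistic),
                 p_value = st$p.value,
                 n1 = length(sample1), n2 = length(sample2)),
            class = "ks_comparison")
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("Two-sample KS comparison: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$ks_distance, x$p_value, x$n1, x$n2))
  invisible(x)
}
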