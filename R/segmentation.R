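#' Segmentation parameters
#'
#' Operator settings for [segment_fas()], mirroring the standard FIJI
#' particle-analysis workflow for focal adhesions: median filtering
#' (radius 1.5 px), rolling-ball background subtraction (radius 50 px)
#' and thresholding at a multiple k of the mean of the
#' background-subtracted image, with k restricted to 9-15.
#'
#' @param median_radius_px median filter radius in pixels (0 disables).
#'   A radius of 1.5 selects the 3x3 neighbourhood.
#' @param rolling_ball_radius_px rolling-ball radius in pixels.
#' @param threshold_multiplier_k numeric in `[9, 15]`, or `"auto"` to
#'   pick the k in 9..15 whose FA count is most stable against k + 1
#'   (plateau heuristic) — a reproducible stand-in for choosing the most
#'   representative threshold by eye.
#' @param min_area_um2 drop components smaller than this (um^2). The
#'   default 0.25 suppresses single-pixel noise at typical calibrations.
#' @param max_area_um2 optional upper area cutoff (um^2), e.g. 15 to
#'   isolate the largest adhesion class.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(median_radius_px = 1.5,
                                rolling_ball_radius_px = 50,
                                threshold_multiplier_k = "auto",
                                min_area_um2 = 0.25,
                                max_area_um2 = NULL) {
  if (median_radius_px < 0) stop("median_radius_px must be >= 0")
  if (rolling_ball_radius_px <= 0) stop("rolling_ball_radius_px must be > 0")
  k <- threshold_multiplier_k
  if (!(identical(k, "auto") ||
        (is.numeric(k) && length(k) == 1L && k >= 9 && k <= 15)))
    stop("threshold_multiplier_k must be \"auto\" or a number in [9, 15]")
  if (min_area_um2 < 0) stop("min_area_um2 must be >= 0")
  if (!is.null(max_area_um2) && max_area_um2 <= min_area_um2)
    stop("max_area_um2 must exceed min_area_um2")
  structure(list(median_radius_px = median_radius_px,
                 rolling_ball_radius_px = rolling_ball_radius_px,
                 threshold_multiplier_k = k,
                 min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2),
            class = "segmentation_params")
}

shift_padded <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' 8-connected component labeling
#'
#' Labels connected foreground regions of a binary raster using
#' 8-connectivity (edge- and corner-adjacent pixels are connected), by
#' iterated minimum-label propagation.
#'
#' @param bw logical or 0/1 matrix.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered 1..n in column-major order of their first pixel.
#' @export
label_components_8 <- function(bw) {
  bw <- bw > 0
  nr <- nrow(bw); nc <- ncol(bw)
  out <- matrix(0L, nr, nc)
  fg <- which(bw)
  n <- length(fg)
  if (n == 0L) return(out)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_len(n)
  r <- (fg - 1L) %% nr + 1L
  cc <- (fg - 1L) %/% nr + 1L
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  # forward neighbours only; each adjacency is visited once
  offs <- cbind(dr = c(1L, 0L, 1L, -1L), dc = c(0L, 1L, 1L, 1L))
  for (o in seq_len(4L)) {
    dr <- offs[o, 1L]; dc <- offs[o, 2L]
    valid <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    nb <- idx[fg[valid] + dr + dc * nr]
    a <- which(valid)[nb > 0L]; b <- nb[nb > 0L]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out[fg] <- match(roots, unique(roots))
  out
}

# Median of each pixel's 3x3 neighbourhood via a 19-comparator sorting
# network on edge-replicated shifts; radii beyond sqrt(2) fall back to
# the constant-time median filter.
median_filter <- function(m, radius_px) {
  if (radius_px <= 0) return(m)
  if (radius_px < 2) return(median3x3(m))
  size <- as.integer(floor(radius_px))
  mx <- max(m)
  if (mx <= 0) return(m)
  as.matrix(EBImage::medianFilter(m / mx, size)) * mx
}

shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

median3x3 <- function(m) {
  p <- list()
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    p[[k]] <- shift_replicate(m, dr, dc)
  }
  cmp <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Paeth's median-of-9 network; the median lands in element 5
  cmp(2, 3); cmp(5, 6); cmp(8, 9); cmp(1, 2); cmp(4, 5); cmp(7, 8)
  cmp(2, 3); cmp(5, 6); cmp(8, 9); cmp(1, 4); cmp(6, 9); cmp(5, 8)
  cmp(4, 7); cmp(2, 5); cmp(3, 6); cmp(5, 8); cmp(5, 3); cmp(7, 5)
  cmp(5, 3)
  p[[5]]
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image by grayscale
#' morphological opening with a flat disc structuring element of the
#' given radius, and subtracts it (clamping at zero). For structures much
#' smaller than the radius this matches the classic rolling-ball
#' estimator: the opening removes everything the disc cannot enter. As
#' in the classic implementation, the background is estimated on a 3x3
#' mean-smoothed copy — an erosion over thousands of pixels otherwise
#' tracks the extreme low tail of the noise and biases the estimate
#' far below the true background.
#'
#' @param m numeric matrix.
#' @param radius_px disc radius in pixels.
#' @param presmooth apply the 3x3 mean filter to the background
#'   estimate's input (the image itself is never smoothed here).
#' @return Background-subtracted matrix (non-negative).
#' @export
subtract_background <- function(m, radius_px = 50, presmooth = TRUE) {
  if (radius_px <= 0) return(m)
  mx <- max(m)
  if (mx <= 0) return(m)
  sm <- if (presmooth)
    as.matrix(EBImage::filter2(m, matrix(1 / 9, 3L, 3L))) else m
  brush <- EBImage::makeBrush(2L * as.integer(floor(radius_px)) + 1L,
                              shape = "disc")
  bg <- as.matrix(EBImage::opening(sm / mx, brush)) * mx
  pmax(m - bg, 0)
}

area_pass <- function(sizes_px, pixel_size_um, params) {
  areas <- sizes_px * pixel_size_um^2
  ok <- areas >= params$min_area_um2
  if (!is.null(params$max_area_um2)) ok <- ok & areas <= params$max_area_um2
  ok
}

count_at_k <- function(sub, k, pixel_size_um, params) {
  labels <- label_components_8(sub > k * mean(sub))
  if (max(labels) == 0L) return(0L)
  sum(area_pass(tabulate(labels[labels > 0L]), pixel_size_um, params))
}

segment_at_k <- function(sub, k, pixel_size_um, params) {
  thr <- k * mean(sub)
  labels <- label_components_8(sub > thr)   # strictly greater than
  n <- max(labels)
  if (n == 0L)
    return(list(labels = labels, fas = empty_fa_table(), threshold = thr))
  fg <- which(labels > 0L)
  ids <- labels[fg]
  keep <- which(area_pass(tabulate(ids, n), pixel_size_um, params))
  out <- matrix(0L, nrow(labels), ncol(labels))
  fas <- empty_fa_table()
  if (length(keep)) {
    nr <- nrow(labels)
    px_by_id <- split(fg, ids)[as.character(keep)]
    rows <- lapply(px_by_id, function(lin) {
      px <- cbind(row = (lin - 1L) %% nr + 1L, col = (lin - 1L) %/% nr + 1L)
      compute_shape_descriptors(px, pixel_size_um)
    })
    relab <- integer(n); relab[keep] <- seq_along(keep)
    out[fg] <- relab[ids]
    fas <- do.call(rbind, rows)
    fas$label <- seq_along(keep)
    rownames(fas) <- NULL
    fas <- fas[, c("label", setdiff(names(fas), "label"))]
  }
  list(labels = out, fas = fas, threshold = thr)
}

empty_fa_table <- function() {
  data.frame(label = integer(), area_um2 = numeric(),
             aspect_ratio = numeric(), centroid_x_um = numeric(),
             centroid_y_um = numeric(), orientation_rad = numeric(),
             major_um = numeric(), minor_um = numeric())
}

#' Segment focal adhesions from a marker channel
#'
#' Applies the particle-analysis pipeline: median filter, rolling-ball
#' background subtraction, threshold at `k` times the mean of the
#' background-subtracted image (strictly greater than), 8-connected
#' component labeling, and an area filter. Shape descriptors are computed
#' per retained component by [compute_shape_descriptors()].
#'
#' @param image an [image_frame()] (FA marker channel).
#' @param params a [segmentation_params()].
#' @return A list with
#'   \describe{
#'     \item{labels}{integer label raster (0 = background).}
#'     \item{fas}{data frame of per-FA descriptors (label, area_um2,
#'       aspect_ratio, centroid, orientation, axes).}
#'     \item{k}{the threshold multiplier actually used.}
#'     \item{threshold}{the absolute intensity threshold.}
#'   }
#' @examples
#' sc <- random_scene_spec(n_fas = 5, seed = 3)
#' img <- generate_cell_image(sc)
#' seg <- segment_fas(img$channels$fa)
#' nrow(seg$fas)
#' @export
segment_fas <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "image_frame"),
            inherits(params, "segmentation_params"))
  ps <- pixel_size(image)
  m <- frame_matrix(image)
  if (all(m == 0))
    return(list(labels = matrix(0L, nrow(m), ncol(m)),
                fas = empty_fa_table(), k = NA_real_, threshold = NA_real_))
  m <- median_filter(m, params$median_radius_px)
  sub <- subtract_background(m, params$rolling_ball_radius_px)
  k <- params$threshold_multiplier_k
  if (identical(k, "auto")) {
    ks <- 9:15
    counts <- vapply(ks, function(kk)
      count_at_k(sub, kk, ps, params), 0L)
    jumps <- abs(diff(counts))
    k <- ks[which.min(jumps)]   # plateau: count changes least vs k+1
  }
  res <- segment_at_k(sub, k, ps, params)
  list(labels = res$labels, fas = res$fas, k = k, threshold = res$threshold)
}
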