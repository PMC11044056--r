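#' Calibrated single-channel image
#'
#' A thin container for a 2D fluorescence raster: a numeric matrix of
#' non-negative intensities plus the physical pixel size in micrometres.
#' Rows index image rows (y, increasing downwards), columns index x; the
#' origin is the top-left corner, matching the usual microscopy raster
#' convention.
#'
#' @param pixels numeric matrix, at least 2x2, non-negative.
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param channel_name optional channel label, e.g. `"paxillin"`.
#' @return An `image_frame` object (a matrix with calibration attributes).
#' @examples
#' img <- image_frame(matrix(runif(64), 8, 8), pixel_size_um = 0.16)
#' pixel_size(img)
#' @export
image_frame <- function(pixels, pixel_size_um, channel_name = "") {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels))
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("an image_frame needs at least 2x2 pixels")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (any(pixels < 0, na.rm = TRUE))
    stop("image intensities must be non-negative")
  structure(pixels,
            pixel_size_um = pixel_size_um,
            channel_name = as.character(channel_name)[1L],
            class = c("image_frame", "matrix", "array"))
}

#' @rdname image_frame
#' @param x an `image_frame` or `fa_movie`.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) stop("object carries no pixel_size_um calibration")
  ps
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image_frame: %d x %d px, %.4g um/px%s\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"),
              if (nzchar(attr(x, "channel_name")))
                paste0(" [", attr(x, "channel_name"), "]") else ""))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

frame_matrix <- function(x) {
  # strip class/attrs so arithmetic stays plain
  m <- unclass(x)
  attr(m, "pixel_size_um") <- NULL
  attr(m, "channel_name") <- NULL
  m
}

#' Two-channel calibrated time-lapse movie
#'
#' Holds the numerator (activity-sensitive) and denominator (abundance
#' reference) channels of a ratiometric biosensor movie as
#' rows x cols x frames arrays, together with the pixel size and the
#' frame interval.
#'
#' @param numerator,denominator 3D numeric arrays of identical dimensions
#'   (rows x cols x frames), non-negative.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @param frame_interval_s time between frames in seconds (> 0).
#' @param channel_names length-2 character vector naming the channels.
#' @return An `fa_movie` object.
#' @export
fa_movie <- function(numerator, denominator, pixel_size_um,
                     frame_interval_s,
                     channel_names = c("csEGFP", "mCherry")) {
  stopifnot(is.array(numerator), is.array(denominator),
            length(dim(numerator)) == 3L,
            identical(dim(numerator), dim(denominator)))
  if (dim(numerator)[3L] < 2L) stop("a movie needs at least 2 frames")
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(list(numerator = numerator, denominator = denominator,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_names = channel_names),
            class = "fa_movie")
}

#' @export
print.fa_movie <- function(x, ...) {
  d <- dim(x$numerator)
  cat(sprintf("fa_movie: %d x %d px, %d frames, %.4g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  cat("  channels:", paste(x$channel_names, collapse = " / "), "\n")
  invisible(x)
}

#' @export
dim.fa_movie <- function(x) dim(x$numerator)

n_frames <- function(movie) dim(movie$numerator)[3L]

movie_frame <- function(movie, channel, t) movie[[channel]][, , t]

#' Read and write calibrated TIFF images and movies
#'
#' Wrappers around the \pkg{tiff} package. TIFF samples are stored in
#' `[0, 1]`, so images are written as `pixels / scale` and rescaled on
#' read; pass the same `scale` to both ends (the writer returns the scale
#' it used, invisibly). Undefined (`NA`/`NaN`) pixels are stored as 0 —
#' quantitative per-pixel output should travel through the CSV writers,
#' the TIFFs are for visual inspection and interchange.
#'
#' @param path file path.
#' @param pixel_size_um pixel size calibration to attach on read.
#' @param channel_name channel label to attach on read.
#' @param image an `image_frame` or plain matrix.
#' @param movie an `fa_movie`.
#' @param scale positive divisor applied before writing; default is the
#'   maximum finite intensity.
#' @param frame_interval_s frame interval to attach when reading a movie.
#' @return `read_image_tiff` returns an [image_frame()]; `read_movie_tiff`
#'   an [fa_movie()] (pages interleaved numerator first:
#'   num1, den1, num2, den2, ...); the writers return `scale` invisibly.
#' @export
read_image_tiff <- function(path, pixel_size_um, channel_name = "",
                            scale = 1) {
  px <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # first sample of RGB-ish data
  image_frame(px * scale, pixel_size_um, channel_name)
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path, scale = NULL) {
  m <- frame_matrix(image)
  if (is.null(scale)) scale <- max(m[is.finite(m)], 1e-12)
  m <- m / scale
  m[!is.finite(m)] <- 0
  tiff::writeTIFF(pmin(pmax(m, 0), 1), path, bits.per.sample = 16L)
  invisible(scale)
}

#' @rdname read_image_tiff
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "fa_movie"))
  nt <- n_frames(movie)
  pages <- vector("list", 2L * nt)
  for (t in seq_len(nt)) {
    pages[[2L * t - 1L]] <- movie$numerator[, , t]
    pages[[2L * t]] <- movie$denominator[, , t]
  }
  if (is.null(scale)) scale <- max(vapply(pages, max, 0), 1e-12)
  pages <- lapply(pages, function(p) pmin(pmax(p / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' @rdname read_image_tiff
#' @export
read_movie_tiff <- function(path, pixel_size_um, frame_interval_s,
                            scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L)
    stop("expected an even number of pages (two interleaved channels)")
  nt <- length(pages) %/% 2L
  d <- dim(pages[[1L]])
  num <- array(0, c(d, nt)); den <- array(0, c(d, nt))
  for (t in seq_len(nt)) {
    num[, , t] <- pages[[2L * t - 1L]] * scale
    den[, , t] <- pages[[2L * t]] * scale
  }
  fa_movie(num, den, pixel_size_um, frame_interval_s)
}
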