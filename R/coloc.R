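coerce_raster <- function(x) {
  if (inherits(x, "image_frame")) frame_matrix(x) else as.matrix(x)
}

masked_pair <- function(A, B, mask) {
  A <- coerce_raster(A); B <- coerce_raster(B)
  if (!identical(dim(A), dim(B))) stop("rasters must have the same shape")
  if (!is.null(mask)) {
    mask <- coerce_raster(mask) > 0
    if (!identical(dim(mask), dim(A)))
      stop("mask must have the same shape as the rasters")
    a <- A[mask]; b <- B[mask]
  } else { a <- as.vector(A); b <- as.vector(B) }
  keep <- is.finite(a) & is.finite(b)
  list(a = a[keep], b = b[keep])
}

#' Pearson correlation of two fluorescence channels
#'
#' Pixel-by-pixel product-moment correlation between two channels,
#' optionally restricted to a mask: 1 for complete positive correlation,
#' -1 for exclusion, 0 for no relationship. Insensitive to gain and
#' offset of either channel.
#'
#' @param A,B rasters ([image_frame()] or matrix) of identical shape.
#' @param mask optional binary raster; statistics use pixels where it is
#'   nonzero.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(A, B, mask = NULL) {
  p <- masked_pair(A, B, mask)
  if (length(p$a) < 2L) stop("need at least 2 masked pixels")
  if (sd(p$a) == 0 || sd(p$b) == 0)
    stop("correlation undefined for a constant channel")
  cor(p$a, p$b)
}

#' Li's intensity correlation quotient (ICQ)
#'
#' The fraction of masked pixels whose mean-centred intensities in the
#' two channels covary positively, minus 0.5: values near +0.5 indicate
#' dependent staining, near 0 random staining, near -0.5 exclusion.
#' Pixels with a zero product (either channel exactly at its mean) are
#' counted as non-positive, i.e. they stay in the denominator.
#'
#' @inheritParams pearson_cc
#' @return ICQ in `[-0.5, 0.5]`.
#' @export
li_icq <- function(A, B, mask = NULL) {
  p <- masked_pair(A, B, mask)
  if (length(p$a) < 2L) stop("need at least 2 masked pixels")
  if (sd(p$a) == 0 || sd(p$b) == 0)
    stop("ICQ undefined for a constant channel")
  prod <- (p$a - mean(p$a)) * (p$b - mean(p$b))
  mean(prod > 0) - 0.5
}

#' Manders overlap coefficients
#'
#' Fractional overlap of two thresholded signals. In the default
#' pixel-count form, `M1` is the fraction of above-threshold A pixels
#' that are also above threshold in B, and `M2` the converse. With
#' `intensity_weighted = TRUE` the classic intensity-weighted form is
#' used instead: `M1 = sum(A over A&B) / sum(A over A)`.
#'
#' @inheritParams pearson_cc
#' @param thrA,thrB channel thresholds (pixels strictly above are
#'   "positive").
#' @param intensity_weighted use the intensity-weighted variant.
#' @return A `coloc_result`-style list: `m1`, `m2`, `thresholds`,
#'   `n_pixels`.
#' @examples
#' A <- matrix(0, 10, 10); A[1:5, ] <- 10
#' B <- matrix(0, 10, 10); B[1:5, 1:5] <- 10
#' manders_overlap(A, B, 1, 1)  # m1 = 0.5, m2 = 1
#' @export
manders_overlap <- function(A, B, thrA, thrB, mask = NULL,
                            intensity_weighted = FALSE) {
  stopifnot(thrA >= 0, thrB >= 0)
  p <- masked_pair(A, B, mask)
  posA <- p$a > thrA; posB <- p$b > thrB
  if (!any(posA)) stop("no above-threshold pixels in channel A")
  if (!any(posB)) stop("no above-threshold pixels in channel B")
  if (intensity_weighted) {
    m1 <- sum(p$a[posA & posB]) / sum(p$a[posA])
    m2 <- sum(p$b[posA & posB]) / sum(p$b[posB])
  } else {
    m1 <- sum(posA & posB) / sum(posA)
    m2 <- sum(posA & posB) / sum(posB)
  }
  list(m1 = m1, m2 = m2, thresholds = c(thrA = thrA, thrB = thrB),
       n_pixels = length(p$a))
}

#' Full colocalization panel
#'
#' Convenience wrapper returning Pearson CC, Li ICQ and Manders M1/M2 in
#' one object. Manders thresholds default to Otsu on each channel.
#'
#' @inheritParams pearson_cc
#' @param thrA,thrB Manders thresholds; `NULL` picks Otsu per channel.
#' @return A `coloc_result` object.
#' @export
coloc_stats <- function(A, B, mask = NULL, thrA = NULL, thrB = NULL) {
  if (is.null(thrA)) thrA <- otsu_threshold(coerce_raster(A))
  if (is.null(thrB)) thrB <- otsu_threshold(coerce_raster(B))
  m <- manders_overlap(A, B, thrA, thrB, mask)
  structure(list(pearson_cc = pearson_cc(A, B, mask),
                 icq = li_icq(A, B, mask),
                 m1 = m$m1, m2 = m$m2,
                 thresholds = m$thresholds, n_pixels = m$n_pixels),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization statistics\n")
  cat(sprintf("  Pearson CC: %7.4f\n", x$pearson_cc))
  cat(sprintf("  Li ICQ:     %7.4f\n", x$icq))
  cat(sprintf("  Manders M1: %7.4f  M2: %7.4f (thr %.3g / %.3g)\n",
              x$m1, x$m2, x$thresholds[1], x$thresholds[2]))
  cat(sprintf("  n pixels:   %d\n", x$n_pixels))
  invisible(x)
}

#' Otsu threshold of a raster
#'
#' @param m numeric matrix.
#' @return Threshold on the intensity scale of `m`.
#' @export
otsu_threshold <- function(m) {
  m <- coerce_raster(m)
  mx <- max(m)
  if (mx <= 0) return(0)
  EBImage::otsu(EBImage::Image(m / mx), range = c(0, 1)) * mx
}

#' FA-masked ratiometric image
#'
#' Reproduces masked ratio imaging: a binary mask is derived from a
#' structural channel (e.g. vinculin), both input channels are
#' multiplied by it, and the pixel-wise ratio numerator/denominator is
#' computed wherever the masked denominator is positive. Pixels outside
#' the mask or with a zero denominator are `NaN` (flagged undefined, not
#' errors).
#'
#' @param numerator,denominator rasters of identical shape.
#' @param mask_source raster used to build the binary mask.
#' @param threshold mask threshold; `NULL` uses Otsu on `mask_source`.
#' @return Matrix of ratios with `NaN` at undefined pixels; attribute
#'   `mask` holds the binary mask used.
#' @export
masked_ratio_image <- function(numerator, denominator, mask_source,
                               threshold = NULL) {
  num <- coerce_raster(numerator); den <- coerce_raster(denominator)
  src <- coerce_raster(mask_source)
  if (!identical(dim(num), dim(den)) || !identical(dim(num), dim(src)))
    stop("all rasters must have the same shape")
  if (is.null(threshold)) threshold <- otsu_threshold(src)
  mask <- src > threshold
  num_m <- num * mask; den_m <- den * mask
  ratio <- matrix(NaN, nrow(num), ncol(num))
  ok <- mask & den_m > 0
  ratio[ok] <- num_m[ok] / den_m[ok]
  attr(ratio, "mask") <- mask
  attr(ratio, "threshold") <- threshold
  ratio
}
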