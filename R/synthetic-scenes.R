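#' Scene specification for synthetic FA images
#'
#' Describes a single synthetic cell: a circular cell of radius
#' `cell_radius_um` centred in the image, decorated with elliptical focal
#' adhesions at known polar positions. The circle gives closed-form
#' ground truth for the relative radial distance (`r_rel`) of every FA,
#' which downstream segmentation tests recover.
#'
#' Angles are measured clockwise from the image "up" direction, matching
#' the convention of [polar_unwrap()]. Each FA must fit inside the cell:
#' `r_rel + (major_um / 2) / cell_radius_um <= 1`.
#'
#' @param image_size_px integer pair (rows, cols).
#' @param pixel_size_um pixel size in micrometres.
#' @param cell_radius_um cell radius in micrometres; the whole cell must
#'   fit in the image.
#' @param fa_specs list of FA descriptions, each created by [fa_spec()].
#' @param background_level background intensity (arbitrary units).
#' @param noise_sigma standard deviation of additive Gaussian read noise.
#' @param psf_sigma_px Gaussian point-spread blur applied after
#'   rendering, in pixels (0 disables blur).
#' @param seed integer seed; all randomness in the generator flows from
#'   it and the caller's RNG state is left untouched.
#' @return A `scene_spec` object (validated list).
#' @seealso [generate_cell_image()], [random_scene_spec()]
#' @export
scene_spec <- function(image_size_px = c(256L, 256L),
                       pixel_size_um = 0.16,
                       cell_radius_um = 15,
                       fa_specs = list(),
                       background_level = 100,
                       noise_sigma = 20,
                       psf_sigma_px = 1,
                       seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 2))
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (psf_sigma_px < 0) stop("psf_sigma_px must be >= 0")
  if (background_level < 0) stop("background_level must be >= 0")
  half_extent_um <- min(image_size_px) / 2 * pixel_size_um
  if (cell_radius_um <= 0 || cell_radius_um > half_extent_um)
    stop("cell_radius_um must be positive and fit inside the image")
  for (fa in fa_specs) {
    stopifnot(inherits(fa, "fa_spec"))
    if (fa$r_rel + (fa$major_um / 2) / cell_radius_um > 1 + 1e-9)
      stop("fa_spec does not fit inside the cell boundary: r_rel + ",
           "semi-major/cell_radius exceeds 1")
  }
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 cell_radius_um = cell_radius_um,
                 fa_specs = fa_specs,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 psf_sigma_px = psf_sigma_px,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param r_rel relative radial position of the FA centre in `[0, 1]`
#'   (0 = cell centre, 1 = periphery).
#' @param angle_rad polar angle, clockwise from "up".
#' @param major_um,minor_um full ellipse axis lengths in micrometres.
#' @param orientation_rad major-axis angle relative to the +x image axis,
#'   y measured upwards (mathematical convention), wrapped to
#'   `[-pi/2, pi/2)`.
#' @param intensity peak FA intensity above background.
#' @export
fa_spec <- function(r_rel, angle_rad, major_um, minor_um,
                    orientation_rad = 0, intensity = 400) {
  stopifnot(r_rel >= 0, r_rel <= 1, major_um > 0, minor_um > 0,
            minor_um <= major_um, intensity > 0)
  structure(list(r_rel = r_rel, angle_rad = angle_rad,
                 major_um = major_um, minor_um = minor_um,
                 orientation_rad = wrap_orientation(orientation_rad),
                 intensity = intensity),
            class = "fa_spec")
}

wrap_orientation <- function(theta) {
  th <- (theta + pi / 2) %% pi - pi / 2
  ifelse(th >= pi / 2, th - pi, th)
}

# Evaluate with a private RNG stream: seeds deterministically, restores
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Polar (r_rel, angle clockwise-from-up) -> pixel coordinates (x=col, y=row),
# 1-based continuous, image centre as cell centre.
scene_centre_px <- function(spec) {
  c(x = (spec$image_size_px[2L] + 1) / 2, y = (spec$image_size_px[1L] + 1) / 2)
}

fa_centre_px <- function(spec, fa) {
  ctr <- scene_centre_px(spec)
  r_px <- fa$r_rel * spec$cell_radius_um / spec$pixel_size_um
  c(x = ctr["x"] + r_px * sin(fa$angle_rad),
    y = ctr["y"] - r_px * cos(fa$angle_rad))
}

# Logical mask of the filled ellipse for one fa_spec.
render_fa_mask <- function(spec, fa, centre_px = fa_centre_px(spec, fa),
                           major_um = fa$major_um) {
  nr <- spec$image_size_px[1L]; nc <- spec$image_size_px[2L]
  a <- major_um / 2 / spec$pixel_size_um
  b <- fa$minor_um / 2 / spec$pixel_size_um
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - centre_px[[1L]]
  y <- -(matrix(seq_len(nr), nr, nc) - centre_px[[2L]])  # y up
  th <- fa$orientation_rad
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

#' Render a synthetic cell image with ground truth
#'
#' Renders the FA marker channel (background + filled ellipses, Gaussian
#' PSF blur, additive Gaussian noise clamped at zero) and an idealized
#' binary whole-cell channel (the cell disc), and returns the planted
#' geometry of every FA. Planted FAs may not overlap — overlapping masks
#' would make the per-FA ground truth ambiguous, so that is an error.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{channels}{list of [image_frame()]s: `fa` (marker) and
#'       `cell` (binary cell disc).}
#'     \item{truth}{data frame of planted FA geometry: one row per FA
#'       with centroid (um), `r_rel`, axes, orientation, analytic ellipse
#'       `area_um2` and `aspect_ratio`.}
#'   }
#' @examples
#' sc <- random_scene_spec(n_fas = 4, seed = 7)
#' img <- generate_cell_image(sc)
#' img$truth[, c("area_um2", "aspect_ratio", "r_rel")]
#' @export
generate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$image_size_px[1L]; nc <- spec$image_size_px[2L]
  signal <- matrix(spec$background_level, nr, nc)
  cover <- matrix(0L, nr, nc)
  truth <- list()
  for (i in seq_along(spec$fa_specs)) {
    fa <- spec$fa_specs[[i]]
    ctr <- fa_centre_px(spec, fa)
    mask <- render_fa_mask(spec, fa, ctr)
    cover <- cover + mask
    signal <- signal + fa$intensity * mask
    truth[[i]] <- data.frame(
      fa = i,
      centroid_x_um = (ctr[[1L]] - 0.5) * spec$pixel_size_um,
      centroid_y_um = (ctr[[2L]] - 0.5) * spec$pixel_size_um,
      r_rel = fa$r_rel, angle_rad = fa$angle_rad,
      major_um = fa$major_um, minor_um = fa$minor_um,
      orientation_rad = fa$orientation_rad,
      area_um2 = pi * (fa$major_um / 2) * (fa$minor_um / 2),
      aspect_ratio = fa$major_um / fa$minor_um,
      intensity = fa$intensity)
  }
  if (any(cover > 1L))
    stop("planted FAs overlap; ground truth would be ambiguous")
  signal <- gaussian_blur(signal, spec$psf_sigma_px)
  noisy <- with_seed(spec$seed,
                     signal + matrix(rnorm(nr * nc, 0, spec$noise_sigma),
                                     nr, nc))
  noisy <- pmax(noisy, 0)
  ctr <- scene_centre_px(spec)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ctr[["x"]]
  y <- matrix(seq_len(nr), nr, nc) - ctr[["y"]]
  cell <- (x^2 + y^2 <= (spec$cell_radius_um / spec$pixel_size_um)^2) * 1
  list(channels = list(
         fa = image_frame(noisy, spec$pixel_size_um, "fa_marker"),
         cell = image_frame(cell, spec$pixel_size_um, "cell_mask")),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(fa = integer(), centroid_x_um = numeric(),
                    centroid_y_um = numeric(), r_rel = numeric(),
                    angle_rad = numeric(), major_um = numeric(),
                    minor_um = numeric(), orientation_rad = numeric(),
                    area_um2 = numeric(), aspect_ratio = numeric(),
                    intensity = numeric()))
}

#' Random non-overlapping scene
#'
#' Draws `n_fas` peripheral FAs with sizes and eccentricities typical of
#' fibroblast adhesions (major axis 1.5-4 um, minor 0.5-1.1 um, roughly
#' radial orientation, r_rel 0.5-0.88) and guarantees non-overlap by
#' enforcing a centre-to-centre spacing of at least the sum of the
#' semi-major axes plus a margin.
#'
#' @param n_fas number of FAs to plant.
#' @param seed integer seed.
#' @param margin_um extra centre spacing margin.
#' @param ... passed on to [scene_spec()].
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(n_fas = 10L, seed = 1L, margin_um = 0.5, ...) {
  base <- scene_spec(seed = seed, ...)
  fas <- with_seed(seed + 104729L, {
    placed <- list(); tries <- 0L
    while (length(placed) < n_fas && tries < 2000L) {
      tries <- tries + 1L
      major <- runif(1, 1.5, 4); minor <- runif(1, 0.5, 1.1)
      r_rel <- runif(1, 0.5, min(0.88, 1 - major / 2 / base$cell_radius_um))
      ang <- runif(1, 0, 2 * pi)
      # radial orientation: major axis along the ray from the cell centre
      radial <- atan2(cos(ang), sin(ang)) + runif(1, -0.2, 0.2)
      cand <- fa_spec(r_rel, ang, major, minor, radial)
      ok <- TRUE
      r_px <- function(f) f$r_rel * base$cell_radius_um
      cx <- r_px(cand) * sin(cand$angle_rad)
      cy <- -r_px(cand) * cos(cand$angle_rad)
      for (p in placed) {
        px <- r_px(p) * sin(p$angle_rad); py <- -r_px(p) * cos(p$angle_rad)
        if (sqrt((cx - px)^2 + (cy - py)^2) <
            (cand$major_um + p$major_um) / 2 + margin_um) { ok <- FALSE; break }
      }
      if (ok) placed[[length(placed) + 1L]] <- cand
    }
    if (length(placed) < n_fas)
      stop("could not place ", n_fas, " non-overlapping FAs; ",
           "reduce n_fas or enlarge the cell")
    placed
  })
  base$fa_specs <- fas
  base
}
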