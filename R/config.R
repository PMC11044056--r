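adhesio_defaults <- function() list(
  # calibration
  pixel_size_um = 0.16, frame_interval_s = 20,
  # segmentation
  median_radius_px = 1.5, rolling_ball_radius_px = 50, k = "auto",
  min_area_um2 = 0.25, max_area_um2 = NULL,
  # biosensor
  max_disp_um = 1, window_min = 5, rate_threshold = 0.02,
  line_width_px = 3, n_positions = 25,
  # screen
  threshold = 6, min_trials = 2, min_tier = "moderate",
  # simulate
  n_fas = 10, n_frames = 20,
  # io
  image = NULL, movie = NULL, a = NULL, b = NULL, mask = NULL,
  cell = NULL, table = NULL, map = NULL, fasta = NULL,
  out = ".", seed = 1L, log_level = "info")

#' Load and validate a run configuration
#'
#' Merges, in increasing priority, the package defaults, an optional
#' YAML config file, and explicit flags, then validates every key.
#' Unknown keys and out-of-range parameters are errors; the threshold
#' multiplier `k` must be `"auto"` or lie in `[9, 15]`.
#'
#' @param path optional YAML file.
#' @param flags named list of overrides (highest priority).
#' @return A validated `run_config` (named list).
#' @examples
#' cfg <- load_config(flags = list(k = 10, seed = 42))
#' cfg$k
#' @export
load_config <- function(path = NULL, flags = list()) {
  cfg <- adhesio_defaults()
  apply_over <- function(cfg, vals, src) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown))
      stop("unknown config key(s) in ", src, ": ",
           paste(unknown, collapse = ", "), "\n  valid keys: ",
           paste(names(cfg), collapse = ", "))
    for (k in names(vals)) cfg[[k]] <- vals[[k]]
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (!is.null(y)) cfg <- apply_over(cfg, y, path)
  }
  cfg <- apply_over(cfg, flags, "flags")
  # range validation (segmentation_params enforces the k in [9,15] rule)
  segmentation_params(cfg$median_radius_px, cfg$rolling_ball_radius_px,
                      cfg$k, cfg$min_area_um2, cfg$max_area_um2)
  if (cfg$pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (cfg$frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (cfg$threshold <= 0) stop("threshold must be > 0")
  if (cfg$min_trials < 1) stop("min_trials must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("seed must be an integer")
  for (p in c("image", "movie", "a", "b", "mask", "cell", "table",
              "map", "fasta"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input path for '", p, "' does not exist: ", cfg[[p]])
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  # polynomial rolling hash of the deparsed config (stays below 2^53 so
  # double arithmetic is exact and the hash is platform-stable); output
  # location and log level do not affect the analysis, so reruns into a
  # different directory produce identical result files
  cfg <- unclass(cfg)
  cfg$out <- NULL
  cfg$log_level <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

adhesio_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[adhesio] ", ...)
}

write_result_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# adhesio %s",
                       as.character(packageVersion("adhesio"))),
               sprintf("# config_hash %s", config_hash(cfg))), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "d")
  path
}

#' Read a result CSV written by the pipeline
#'
#' @param path CSV with `#` header comments.
#' @return Data frame.
#' @export
read_result_csv <- function(path)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)

column_map_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y, function(e)
    data.frame(column = e$column, condition = e$condition,
               trial = if (is.null(e$trial)) NA_integer_ else
                 as.integer(e$trial))))
}

#' Run a pipeline stage
#'
#' Dispatches one subcommand — `simulate`, `segment`, `coloc`,
#' `biosensor`, `screen` or `motifs` — writing its artifacts under
#' `config$out`. Runs are deterministic given the config (which embeds
#' the seed); every output CSV starts with comment lines carrying the
#' tool version and a hash of the effective config, and the effective
#' config itself is echoed to `config_used.yaml` beside the outputs.
#'
#' @param subcommand stage name.
#' @param config a [load_config()] result.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(subcommand, config) {
  subcommand <- match.arg(subcommand, c("simulate", "segment", "coloc",
                                        "biosensor", "screen", "motifs"))
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out, f)
  written <- character(0)
  echo <- out("config_used.yaml")
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain[!vapply(cfg_plain, is.null, TRUE)], echo)
  written <- c(written, echo)
  params <- segmentation_params(config$median_radius_px,
                                config$rolling_ball_radius_px, config$k,
                                config$min_area_um2, config$max_area_um2)
  if (subcommand == "simulate") {
    sc <- random_scene_spec(n_fas = config$n_fas, seed = config$seed,
                            pixel_size_um = config$pixel_size_um)
    img <- generate_cell_image(sc)
    scale <- write_image_tiff(img$channels$fa, out("scene_fa.tif"))
    write_image_tiff(img$channels$cell, out("scene_cell.tif"), scale = 1)
    truth <- img$truth
    truth$tiff_scale <- scale
    write_result_csv(truth, out("scene_truth.csv"), config)
    written <- c(written, out("scene_fa.tif"), out("scene_cell.tif"),
                 out("scene_truth.csv"))
  } else if (subcommand == "segment") {
    if (is.null(config$image)) stop("segment requires an 'image' path")
    img <- read_image_tiff(config$image, config$pixel_size_um)
    seg <- segment_fas(img, params)
    cell <- if (!is.null(config$cell))
      read_image_tiff(config$cell, config$pixel_size_um) else NULL
    fas <- if (nrow(seg$fas))
      fa_radial_distances(seg, cell, config$pixel_size_um) else seg$fas
    write_result_csv(fas, out("fa.csv"), config)
    adhesio_log(config, sprintf("segment: %d FAs at k = %s", nrow(fas),
                                format(seg$k)))
    written <- c(written, out("fa.csv"))
  } else if (subcommand == "coloc") {
    if (is.null(config$a) || is.null(config$b))
      stop("coloc requires 'a' and 'b' image paths")
    A <- read_image_tiff(config$a, config$pixel_size_um)
    B <- read_image_tiff(config$b, config$pixel_size_um)
    mask <- if (!is.null(config$mask))
      read_image_tiff(config$mask, config$pixel_size_um) else NULL
    cs <- coloc_stats(A, B, mask)
    df <- data.frame(pearson_cc = cs$pearson_cc, icq = cs$icq,
                     m1 = cs$m1, m2 = cs$m2, n_pixels = cs$n_pixels)
    write_result_csv(df, out("coloc.csv"), config)
    ratio <- masked_ratio_image(frame_matrix(A), frame_matrix(B),
                                frame_matrix(B))
    write_image_tiff(image_frame(ifelse(is.finite(ratio), ratio, 0),
                                 config$pixel_size_um),
                     out("ratio.tif"))
    written <- c(written, out("coloc.csv"), out("ratio.tif"))
  } else if (subcommand == "biosensor") {
    if (is.null(config$movie)) stop("biosensor requires a 'movie' path")
    mv <- read_movie_tiff(config$movie, config$pixel_size_um,
                          config$frame_interval_s)
    res <- analyze_biosensor_movie(mv, params,
                                   max_disp_um = config$max_disp_um,
                                   window_min = config$window_min,
                                   rate_threshold = config$rate_threshold)
    write_result_csv(res$series, out("ratio_series.csv"), config)
    write_result_csv(res$segments, out("growth_segments.csv"), config)
    written <- c(written, out("ratio_series.csv"),
                 out("growth_segments.csv"))
  } else if (subcommand == "screen") {
    if (is.null(config$table) || is.null(config$map))
      stop("screen requires 'table' and 'map' paths")
    tab <- load_quant_table(config$table, column_map_from_yaml(config$map))
    hl <- screen_hits(tab, config$threshold, config$min_trials)
    write_result_csv(hl$hits, out("hits.csv"), config)
    adhesio_log(config, sprintf("screen: %d hits", hl$n_hits))
    written <- c(written, out("hits.csv"))
  } else if (subcommand == "motifs") {
    if (is.null(config$fasta)) stop("motifs requires a 'fasta' path")
    mh <- scan_fasta_pka_motifs(config$fasta, config$min_tier)
    write_result_csv(mh, out("motifs.csv"), config)
    written <- c(written, out("motifs.csv"))
  }
  invisible(written)
}

#' Segment, track and summarize a biosensor movie
#'
#' The full biosensor chain on a two-channel movie: per-frame FA
#' segmentation of the denominator channel, nearest-centroid tracking,
#' per-track sum/sum ratio series with boxcar smoothing, and growth
#' classification of each track.
#'
#' @param movie an [fa_movie()].
#' @param params a [segmentation_params()].
#' @param max_disp_um tracking gate (um per frame).
#' @param window_min,rate_threshold growth-classifier settings.
#' @param background_radius rolling-ball radius used for the ratio
#'   channels (defaults to the segmentation rolling-ball radius).
#' @return List: `tracks`, `series` (long data frame: track, frame,
#'   time_s, raw_ratio, smoothed_ratio), `segments` (long data frame of
#'   growth segments per track), `series_objects`, `state_objects`.
#' @export
analyze_biosensor_movie <- function(movie, params = segmentation_params(),
                                    max_disp_um = 1, window_min = 5,
                                    rate_threshold = 0.02,
                                    background_radius =
                                      params$rolling_ball_radius_px) {
  nt <- n_frames(movie)
  segs <- vector("list", nt); labels <- vector("list", nt)
  for (t in seq_len(nt)) {
    s <- segment_fas(image_frame(movie$denominator[, , t],
                                 movie$pixel_size_um), params)
    segs[[t]] <- s$fas; labels[[t]] <- s$labels
  }
  tracks <- track_fas(segs, max_disp_um = max_disp_um)
  series_rows <- list(); seg_rows <- list()
  series_objects <- list(); state_objects <- list()
  for (tr in tracks) {
    id <- attr(tr, "track_id")
    rs <- compute_ratio_series(movie, tr, labels,
                               background_radius = background_radius)
    gs <- classify_growth_track(tr, movie$frame_interval_s,
                                window_min, rate_threshold)
    series_objects[[id]] <- rs; state_objects[[id]] <- gs
    series_rows[[id]] <- data.frame(track = id, frame = tr$frame,
                                    time_s = rs$times_s,
                                    raw_ratio = rs$raw_ratio,
                                    smoothed_ratio = rs$smoothed_ratio,
                                    length_um = tr$length_um)
    if (nrow(gs$segments))
      seg_rows[[id]] <- cbind(track = id, gs$segments)
  }
  list(tracks = tracks,
       series = do.call(rbind, series_rows),
       segments = if (length(seg_rows)) do.call(rbind, seg_rows) else
         data.frame(track = integer(), t_start = numeric(),
                    t_end = numeric(), rate_um_per_min = numeric(),
                    class = character()),
       series_objects = series_objects, state_objects = state_objects)
}
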