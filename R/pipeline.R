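#' Run configuration for batch processing
#'
#' Bundles paths and every pipeline parameter so that one fixed
#' configuration is applied identically across all chunks and videos of
#' an experiment (parameters must be held constant within an experiment
#' for the numbers to be comparable).
#'
#' @param video1,video2 Frame directories for views 1 and 2.
#' @param matrix1,matrix2 Plain-text 3x4 projection-matrix files (only
#'   needed when 3D tracking is wanted).
#' @param out_dir Output directory for CSVs and the log.
#' @param threshold Foreground threshold `T`, levels.
#' @param alpha Background adaptation rate.
#' @param sample_fraction Fraction of frames sampled for background
#'   initialization.
#' @param min_component_size Minimum silhouette size, pixels.
#' @param connectivity 4 or 8.
#' @param channel Detection channel.
#' @param bin_edges Intensity bin edges (see [default_bin_edges]).
#' @param report_bins Bins pooled into the fluorescence time course
#'   (G3+G4 by default, the high-intensity reporter bins).
#' @param empty_frames `"zero"` counts frames with no detection as 0
#'   fluorescence (an animal at rest long enough joins the background, so
#'   this under-counts conservatively); `"skip"` drops them from the
#'   per-minute means.
#' @param loess_span,loess_degree LOESS smoothing parameters for the
#'   per-minute series.
#' @param angle_threshold Heading-change angle, degrees.
#' @param frame_rate Frames per second.
#' @param max_frame_gap Largest frame gap treated as continuous motion.
#' @param chunk_frames Frames per processing chunk; the default is one
#'   hour of 30 fps video (108,000 frames), the historical size of one
#'   recorded file.
#' @return Object of class `run_config`.
#' @export
run_config <- function(video1, video2, matrix1 = NULL, matrix2 = NULL,
                       out_dir = "fluotrack_out", threshold = 40,
                       alpha = 0.05, sample_fraction = 0.01,
                       min_component_size = 4, connectivity = 8,
                       channel = "green", bin_edges = default_bin_edges,
                       report_bins = c(3, 4),
                       empty_frames = c("zero", "skip"),
                       loess_span = 0.1, loess_degree = 2,
                       angle_threshold = 90, frame_rate = 30,
                       max_frame_gap = 30,
                       chunk_frames = frames_per_chunk(30)) {
  cfg <- list(video1 = video1, video2 = video2,
              matrix1 = matrix1, matrix2 = matrix2, out_dir = out_dir,
              threshold = threshold, alpha = alpha,
              sample_fraction = sample_fraction,
              min_component_size = min_component_size,
              connectivity = connectivity,
              channel = match.arg(channel, .CHANNELS),
              bin_edges = bin_edges, report_bins = sort(report_bins),
              empty_frames = match.arg(empty_frames),
              loess_span = loess_span, loess_degree = loess_degree,
              angle_threshold = angle_threshold, frame_rate = frame_rate,
              max_frame_gap = max_frame_gap,
              chunk_frames = as.integer(chunk_frames))
  stopifnot(cfg$threshold > 0, cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$min_component_size >= 0, cfg$connectivity %in% c(4, 8),
            cfg$frame_rate > 0, cfg$chunk_frames >= 1,
            all(cfg$report_bins %in% 1:4))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of `run_config()` keys.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_fluotrack("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

config_hash <- function(config) {
  fnv1a(paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}

# parameters analyze_view needs, with run_config defaults
view_params <- function(config = NULL) {
  defaults <- list(threshold = 40, alpha = 0.05, sample_fraction = 0.01,
                   min_component_size = 4, connectivity = 8,
                   channel = "green", bin_edges = default_bin_edges)
  if (is.null(config)) return(defaults)
  utils::modifyList(defaults, config[intersect(names(defaults),
                                               names(config))])
}

#' Detect and quantify silhouettes in one view
#'
#' The per-view core of the pipeline: for every frame, classify against
#' the running background, update the model selectively, clean the mask
#' by 3x3 opening, extract size-filtered connected components, and record
#' each component's centroid plus its four-bin histogram (counts and
#' intensity sums) on all three channels.
#'
#' @param frames A [frame_sequence()], frame list, or frame directory.
#' @param config Optional [run_config()] (or named list) supplying
#'   threshold, alpha, sample_fraction, min_component_size, connectivity,
#'   channel and bin_edges; unsupplied keys use the defaults.
#' @param model A [background_model()] to continue from; by default one
#'   is initialized from this source. Pass the model returned by the
#'   previous chunk to stream long recordings in pieces.
#' @param view_id View identifier recorded in the output.
#' @param frame_offset Added to frame indices in the output (for
#'   chunked processing).
#' @return List: `detections` (one row per retained component: frame,
#'   view, component_id, size_px, centroid_row, centroid_col, bbox, and
#'   per-channel bin sums `R1..B4` with matching counts `n_R1..n_B4`),
#'   `model` (updated background), `n_frames`.
#' @export
analyze_view <- function(frames, config = NULL, model = NULL,
                         view_id = 1L, frame_offset = 0L) {
  p <- view_params(config)
  src <- open_frame_source(frames)
  if (is.null(model))
    model <- initialize_background(src, p$sample_fraction, p$alpha,
                                   p$threshold, p$channel)
  bin_names <- paste0(rep(c("R", "G", "B"), each = 4), 1:4)
  rows <- list()
  for (i in seq_len(src$n)) {
    fr <- src$get(i)
    fidx <- i + frame_offset
    mask <- classify_frame(fr, model, fidx)
    model <- update_background(model, fr, mask)
    comps <- label_components(morphological_open(mask), p$connectivity,
                              fidx, view_id)
    comps <- filter_components(comps, p$min_component_size)
    for (k in seq_along(comps)) {
      co <- comps[[k]]
      hs <- lapply(.CHANNELS, function(chn)
        bin_component_intensities(fr, co, chn, p$bin_edges))
      sums <- unlist(lapply(hs, `[[`, "intensity_sums"))
      counts <- unlist(lapply(hs, `[[`, "counts"))
      row <- data.frame(frame = fidx, view = view_id, component_id = k,
                        size_px = co$size,
                        centroid_row = co$centroid[1],
                        centroid_col = co$centroid[2],
                        bbox_min_row = co$bounding_box[1],
                        bbox_min_col = co$bounding_box[2],
                        bbox_max_row = co$bounding_box[3],
                        bbox_max_col = co$bounding_box[4],
                        row.names = NULL)
      row[bin_names] <- as.list(sums)
      row[paste0("n_", bin_names)] <- as.list(as.integer(counts))
      rows[[length(rows) + 1L]] <- row
    }
  }
  detections <- if (length(rows)) do.call(rbind, rows) else
    empty_detections(bin_names)
  list(detections = detections, model = model, n_frames = src$n)
}

empty_detections <- function(bin_names) {
  d <- data.frame(frame = integer(), view = integer(),
                  component_id = integer(), size_px = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  bbox_min_row = integer(), bbox_min_col = integer(),
                  bbox_max_row = integer(), bbox_max_col = integer())
  d[bin_names] <- lapply(bin_names, function(x) numeric())
  d[paste0("n_", bin_names)] <- lapply(bin_names, function(x) integer())
  d
}

#' Pooled fluorescence time course from detections
#'
#' Per frame, sums the selected-bin intensity sums over every retained
#' component in both views (the detected animal or group of animals);
#' then averages per minute and smooths with LOESS. Frames with no
#' detection read 0 (or are skipped, per `empty_frames`).
#'
#' @param detections Detections table from [analyze_view()] (both views
#'   may be row-bound together).
#' @param n_frames Total frame count of the recording.
#' @param frame_rate Frames per second.
#' @param channel Reporter channel for the time course.
#' @param report_bins Bins pooled into the value (default G3+G4).
#' @param empty_frames `"zero"` or `"skip"` (see [run_config()]).
#' @param span,degree LOESS parameters; smoothing is skipped (with `NA`
#'   column) when the per-minute series is too short for the fit.
#' @return List: `per_frame` (frame, value), `per_minute` (minute,
#'   raw_mean, loess_mean), `bins`, `channel`.
#' @export
fluorescence_series <- function(detections, n_frames,
                                frame_rate = 30, channel = "green",
                                report_bins = c(3, 4),
                                empty_frames = c("zero", "skip"),
                                span = 0.1, degree = 2) {
  empty_frames <- match.arg(empty_frames)
  pre <- c(red = "R", green = "G", blue = "B")[
    match.arg(channel, .CHANNELS)]
  cols <- paste0(pre, sort(report_bins))
  per_frame <- rep(if (empty_frames == "zero") 0 else NA_real_, n_frames)
  if (nrow(detections)) {
    vals <- rowSums(detections[, cols, drop = FALSE])
    agg <- tapply(vals, detections$frame, sum)
    per_frame[as.integer(names(agg))] <- as.numeric(agg)
  }
  raw <- aggregate_per_minute(per_frame, frame_rate)
  sm <- tryCatch(loess_smooth(raw, span, degree),
                 error = function(e) rep(NA_real_, length(raw)))
  list(per_frame = data.frame(frame = seq_len(n_frames),
                              value = per_frame),
       per_minute = data.frame(minute = seq_along(raw), raw_mean = raw,
                               loess_mean = sm),
       bins = sort(report_bins), channel = match.arg(channel, .CHANNELS))
}

#' Write threshold-preview masks
#'
#' Renders the binary change mask of each frame at a candidate threshold
#' as PNG images, the command-line stand-in for interactively sliding the
#' threshold until animals, and only animals, light up.
#'
#' @param video Frame directory (or sequence).
#' @param threshold Candidate threshold, levels.
#' @param out_dir Directory for mask PNGs.
#' @param config Optional [run_config()] for the remaining parameters.
#' @param max_frames Preview at most this many frames.
#' @return Invisibly, the written paths.
#' @export
preview_threshold <- function(video, threshold, out_dir, config = NULL,
                              max_frames = 50L) {
  p <- view_params(config)
  src <- open_frame_source(video)
  model <- initialize_background(src, p$sample_fraction, p$alpha,
                                 threshold, p$channel)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- min(src$n, max_frames)
  paths <- character(n)
  for (i in seq_len(n)) {
    fr <- src$get(i)
    mask <- classify_frame(fr, model, i)
    model <- update_background(model, fr, mask)
    paths[i] <- file.path(out_dir, sprintf("mask_%06d.png", i))
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                  paths[i])
  }
  invisible(paths)
}

write_csv_prov <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fluotrack %s config %s",
                     as.character(utils::packageVersion("fluotrack")), hash),
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, skipping provenance comment lines
#'
#' @param path CSV written by [run_batch()].
#' @return Data frame.
#' @export
read_output_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Batch-process a two-view recording
#'
#' The full pipeline over a pair of frame directories: a single
#' background model per view is initialized by even sampling over the
#' *whole* recording, then frames are processed in chunks of
#' `chunk_frames` with the model carried across chunk boundaries, so
#' outputs are identical however the recording is chunked. Emits
#' detection, fluorescence, per-minute, trajectory and summary CSVs (each
#' with a provenance header comment) plus a structured log with
#' per-chunk detection counts and pairing skip reasons.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output file paths and the in-memory
#'   results (`detections`, `pairs`, `track`, `fluor`, `summary`).
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- sprintf("run_batch start: config %s", hash)
  src <- lapply(c(config$video1, config$video2), open_frame_source,
                frame_rate = config$frame_rate)
  models <- lapply(src, function(s)
    initialize_background(s, config$sample_fraction, config$alpha,
                          config$threshold, config$channel))
  det <- list()
  for (view in 1:2) {
    s <- src[[view]]
    starts <- seq(1L, s$n, by = config$chunk_frames)
    for (cs in starts) {
      ce <- min(cs + config$chunk_frames - 1L, s$n)
      chunk <- new_frame_source(ce - cs + 1L, s$frame_rate,
                                function(i) s$get(i + cs - 1L), s$dim)
      res <- analyze_view(chunk, config, model = models[[view]],
                          view_id = view, frame_offset = cs - 1L)
      models[[view]] <- res$model
      det[[length(det) + 1L]] <- res$detections
      log_lines <- c(log_lines,
                     sprintf("view %d chunk %d-%d: %d components",
                             view, cs, ce, nrow(res$detections)))
    }
  }
  detections <- do.call(rbind, det)
  paths <- list(detections = file.path(config$out_dir, "detections.csv"),
                fluorescence = file.path(config$out_dir, "fluorescence.csv"),
                per_minute = file.path(config$out_dir, "per_minute.csv"),
                trajectory = file.path(config$out_dir, "trajectory.csv"),
                summary = file.path(config$out_dir, "summary.csv"),
                log = file.path(config$out_dir, "run.log"))
  geom_cols <- c("frame", "view", "component_id", "size_px",
                 "centroid_row", "centroid_col", "bbox_min_row",
                 "bbox_min_col", "bbox_max_row", "bbox_max_col")
  write_csv_prov(detections[, geom_cols], paths$detections, hash)
  write_csv_prov(detections, paths$fluorescence, hash)

  n_frames <- max(vapply(src, `[[`, numeric(1), "n"))
  fluor <- fluorescence_series(detections, n_frames, config$frame_rate,
                               config$channel, config$report_bins,
                               config$empty_frames, config$loess_span,
                               config$loess_degree)
  write_csv_prov(fluor$per_minute, paths$per_minute, hash)

  track <- NULL; summ <- NULL; pairs <- NULL
  if (!is.null(config$matrix1) && !is.null(config$matrix2)) {
    cam1 <- load_projection_matrix(config$matrix1, 1L)
    cam2 <- load_projection_matrix(config$matrix2, 2L)
    pairs <- pair_observations(detections[detections$view == 1L, ],
                               detections[detections$view == 2L, ])
    log_lines <- c(log_lines,
                   sprintf("pairing: %d pairs; skipped %s",
                           nrow(pairs$pairs),
                           paste(names(pairs$skipped), pairs$skipped,
                                 sep = "=", collapse = ", ")))
    track <- reconstruct_trajectory(pairs, cam1, cam2, config$frame_rate)
    write_csv_prov(as.data.frame(track), paths$trajectory, hash)
    summ <- motion_summary(track, config$frame_rate,
                           config$angle_threshold, config$max_frame_gap)
    write_csv_prov(data.frame(n_points = summ$n_points,
                              mean_speed = summ$mean_speed,
                              max_speed = summ$max_speed,
                              path_length = summ$path_length,
                              heading_change_freq = summ$heading_change_freq),
                   paths$summary, hash)
  }
  writeLines(c(log_lines, "run_batch done"), paths$log)
  invisible(list(paths = paths, detections = detections, pairs = pairs,
                 track = track, fluor = fluor, summary = summ))
}
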