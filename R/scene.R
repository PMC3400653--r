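#' Synthetic scene configuration
#'
#' Describes a two-view test scene: a cylindrical observation chamber
#' (proportioned like a culture vial, height about three times the
#' radius) containing one or more bright fluorescent blobs moving against
#' a dark, noisy background, imaged by two pinhole cameras. World units
#' are arbitrary; the defaults read naturally as millimetres for a
#' standard glass vial.
#'
#' @param image_height,image_width Frame size in pixels.
#' @param frame_rate Frames per second (may be fractional for slow
#'   time-lapse scenes).
#' @param n_frames Number of frames (>= 2).
#' @param chamber_radius,chamber_height Cylinder dimensions, world units;
#'   the cylinder axis is the world z axis with the floor at z = 0.
#' @param blob_radius_world Physical blob radius, world units.
#' @param blob_peak_intensity Peak added intensity per channel (levels
#'   0--255); scalar or length-3 `(red, green, blue)`. The green-heavy
#'   default mimics a GFP reporter with faint bleed-through.
#' @param background_level Mean background level (levels).
#' @param noise_sd Gaussian noise standard deviation (levels); clipped,
#'   not wrapped, at 0 and 255.
#' @param random_seed Integer seed; identical configs render bit-identical
#'   frame stacks.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(image_height = 240, image_width = 320,
                         frame_rate = 30, n_frames = 600,
                         chamber_radius = 12.5, chamber_height = 37.5,
                         blob_radius_world = 1.5,
                         blob_peak_intensity = c(30, 200, 30),
                         background_level = 10, noise_sd = 2,
                         random_seed = 1L) {
  if (length(blob_peak_intensity) == 1L)
    blob_peak_intensity <- rep(blob_peak_intensity, 3L)
  stopifnot(length(blob_peak_intensity) == 3L)
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              frame_rate = frame_rate, n_frames = as.integer(n_frames),
              chamber_radius = chamber_radius,
              chamber_height = chamber_height,
              blob_radius_world = blob_radius_world,
              blob_peak_intensity = as.numeric(blob_peak_intensity),
              background_level = background_level, noise_sd = noise_sd,
              random_seed = as.integer(random_seed))
  with(cfg, {
    if (n_frames < 2L) stop_fluotrack("n_frames must be >= 2")
    if (any(c(image_height, image_width, frame_rate, chamber_radius,
              chamber_height, blob_radius_world) <= 0))
      stop_fluotrack("all scene dimensions and rates must be positive")
    if (noise_sd < 0 || background_level < 0 || background_level > 255)
      stop_fluotrack("background_level must be in [0, 255] and noise_sd >= 0")
    if (max(blob_peak_intensity) <= background_level + 3 * noise_sd)
      stop_fluotrack("blobs are undetectable by construction: need peak intensity > background_level + 3 * noise_sd")
  })
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0("<scene_config: %d frames %dx%d @ %.4g fps; chamber r=%.3g h=%.3g;",
                     " blob peak (%s), bg %.3g, noise sd %.3g, seed %d>\n"),
              x$n_frames, x$image_height, x$image_width, x$frame_rate,
              x$chamber_radius, x$chamber_height,
              paste(x$blob_peak_intensity, collapse = ","),
              x$background_level, x$noise_sd, x$random_seed))
  invisible(x)
}

#' Default two-camera rig for a scene
#'
#' Two cameras at right angles on the chamber equator, both aimed at the
#' cylinder axis at mid-height, with focal length chosen so the chamber
#' fills most of the frame.
#'
#' @param config A [scene_config()].
#' @param distance Camera distance from the cylinder axis (world units).
#' @param focal_length Focal length in pixels; default scales with
#'   `distance` so the chamber projects inside the frame.
#' @return List of two [camera_model()] objects (view_id 1 and 2).
#' @export
default_cameras <- function(config, distance = 6 * config$chamber_radius,
                            focal_length = 3.5 * distance) {
  h2 <- config$chamber_height / 2
  pp <- c((config$image_width - 1) / 2, (config$image_height - 1) / 2)
  # rows of R: camera right, down (world -z), forward
  r1 <- make_camera(focal_length, pp,
                    rbind(c(0, 1, 0), c(0, 0, -1), c(-1, 0, 0)),
                    c(distance, 0, h2), view_id = 1L)
  r2 <- make_camera(focal_length, pp,
                    rbind(c(-1, 0, 0), c(0, 0, -1), c(0, -1, 0)),
                    c(0, distance, h2), view_id = 2L)
  list(r1, r2)
}

#' Generate a blob trajectory inside the chamber
#'
#' @param kind One of `"helix"` (steady climb around the axis, echoing a
#'   fly circling the vial wall), `"bounded-random-walk"` (reflected
#'   Gaussian steps, seeded from the scene seed) or `"stationary"`.
#' @param config A [scene_config()].
#' @param radius Helix radius (defaults to 70% of the chamber radius).
#' @param turns Helix revolutions over the whole sequence.
#' @param step_sd Random-walk per-axis step SD, world units.
#' @param start Optional starting point (stationary position, walk start).
#' @return `n_frames x 3` matrix of world points, all inside the
#'   cylinder.
#' @export
make_trajectory <- function(kind = c("helix", "bounded-random-walk",
                                     "stationary"),
                            config, radius = 0.7 * config$chamber_radius,
                            turns = 3, step_sd = 0.08 * config$chamber_radius,
                            start = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "scene_config"))
  n <- config$n_frames
  R <- config$chamber_radius; H <- config$chamber_height
  if (kind == "stationary") {
    p <- if (is.null(start)) c(0.5 * R, 0, 0.4 * H) else start
    return(matrix(rep(p, each = n), n, 3))
  }
  if (kind == "helix") {
    if (radius >= R) stop_fluotrack("helix radius must be inside the chamber")
    th <- seq(0, turns * 2 * pi, length.out = n)
    z <- seq(0.15 * H, 0.85 * H, length.out = n)
    return(cbind(radius * cos(th), radius * sin(th), z))
  }
  # bounded-random-walk: reflected at the cylinder wall, floor and ceiling
  out <- matrix(0, n, 3)
  out[1, ] <- if (is.null(start)) c(0, 0, H / 2) else start
  local_seed(config$random_seed, {
    steps <- matrix(rnorm(3 * (n - 1), sd = step_sd), n - 1, 3)
    for (i in 2:n) {
      p <- out[i - 1, ] + steps[i - 1, ]
      rho <- sqrt(sum(p[1:2]^2))
      rmax <- 0.95 * R
      if (rho > rmax) p[1:2] <- p[1:2] * (2 * rmax - rho) / rho
      if (p[3] < 0.05 * H) p[3] <- 2 * 0.05 * H - p[3]
      if (p[3] > 0.95 * H) p[3] <- 2 * 0.95 * H - p[3]
      out[i, ] <- p
    }
  })
  out
}

# run code with a temporarily-seeded RNG, restoring global state after
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# deterministic per-(scene, view, frame) seed so streamed, chunked and
# in-memory renderings agree bit-for-bit; LCG scramble kept under 2^31
frame_seed <- function(config, view, i) {
  k <- (config$random_seed %% 65536) + 7919 * view + i
  as.integer((1103515245 * (k %% 65536) + 12345 + k %/% 65536) %% 2147483647)
}

# analytic speed of the helix trajectory (world units / second)
helix_speed <- function(config, radius = 0.7 * config$chamber_radius,
                        turns = 3) {
  n <- config$n_frames
  dth <- turns * 2 * pi / (n - 1)
  dz <- 0.7 * config$chamber_height / (n - 1)
  # chord per frame: 2 r sin(dth/2) horizontally, dz vertically
  sqrt((2 * radius * sin(dth / 2))^2 + dz^2) * config$frame_rate
}

# --- rendering ----------------------------------------------------------

# projected blob footprint: isotropic Gaussian spot; sigma from projected
# physical radius, floored so the above-threshold footprint spans >= 9 px
blob_sigma_px <- function(focal_equiv, depth, blob_radius_world) {
  max(0.5 * focal_equiv * blob_radius_world / depth, 1.2)
}

render_one_frame <- function(i, view, camera, trajectories, config,
                             truth_rows = FALSE,
                             intensity_profiles = NULL) {
  H <- config$image_height; W <- config$image_width
  local_seed(frame_seed(config, view, i), {
    base <- config$background_level +
      if (config$noise_sd > 0) rnorm(H * W * 3, sd = config$noise_sd) else 0
    frame <- array(base, c(H, W, 3L))
    truth <- NULL
    # focal-equivalent scale for sigma: |P h1| relative to bottom row scale
    Pn <- camera$P
    f_equiv <- sqrt(sum(Pn[1, 1:3]^2) / sum(Pn[3, 1:3]^2) -
                    (sum(Pn[1, 1:3] * Pn[3, 1:3]) / sum(Pn[3, 1:3]^2))^2)
    for (b in seq_along(trajectories)) {
      X <- trajectories[[b]][i, ]
      uv <- project_point(camera, X)
      in_view <- uv[1] >= 0 && uv[1] <= W - 1 && uv[2] >= 0 && uv[2] <= H - 1
      isum <- c(0, 0, 0)
      scale_b <- if (is.null(intensity_profiles)) 1
                 else intensity_profiles[[b]][i]
      if (in_view) {
        depth <- sqrt(sum((X - camera$center)^2))
        sig <- blob_sigma_px(f_equiv, depth, config$blob_radius_world)
        r0 <- uv[2] + 1; c0 <- uv[1] + 1   # continuous 1-based row/col
        half <- ceiling(4 * sig)
        rows <- max(1, floor(r0 - half)):min(H, ceiling(r0 + half))
        cols <- max(1, floor(c0 - half)):min(W, ceiling(c0 + half))
        g <- exp(-(outer((rows - r0)^2, (cols - c0)^2, "+")) / (2 * sig^2))
        for (ch in 1:3) {
          add <- scale_b * config$blob_peak_intensity[ch] * g
          frame[rows, cols, ch] <- frame[rows, cols, ch] + add
          isum[ch] <- sum(add)
        }
      }
      if (truth_rows)
        truth <- rbind(truth, data.frame(
          frame = i, blob_id = b, x = X[1], y = X[2], z = X[3],
          u = uv[1], v = uv[2], in_view = in_view,
          isum_red = isum[1], isum_green = isum[2], isum_blue = isum[3]))
    }
    frame <- array(as.integer(pmin(255, pmax(0, round(frame)))), dim(frame))
    if (truth_rows) list(frame = frame, truth = truth) else frame
  })
}

#' Render a two-view synthetic sequence with ground truth
#'
#' Renders each frame as `background_level` plus clipped Gaussian noise
#' plus, per blob, an isotropic Gaussian-profile spot centred at the
#' blob's projected position (peak `blob_peak_intensity`, width from the
#' projected physical radius, floored so the detectable footprint spans
#' at least 9 pixels). Blobs whose projected centre falls outside a view
#' are rendered blob-free there and flagged, mirroring real frames where
#' an animal is invisible to one camera.
#'
#' @param trajectories List of `n_frames x 3` world-point matrices, one
#'   per blob (see [make_trajectory()]).
#' @param cameras List of two [camera_model()] objects.
#' @param config A [scene_config()].
#' @param intensity_profiles Optional list (one numeric length-`n_frames`
#'   vector per blob) of multipliers on `blob_peak_intensity`, for
#'   emulating reporter induction time courses; default constant 1.
#' @return List with `view1`, `view2` (each a [frame_sequence()]) and
#'   `truth`, a data frame with one row per (frame, blob): true 3D
#'   position, per-view projected pixel, in-view flags and the rendered
#'   (pre-noise, unclipped) intensity sum per channel in each view.
#' @export
render_sequence <- function(trajectories, cameras, config,
                            intensity_profiles = NULL) {
  check_scene_args(trajectories, cameras, config, intensity_profiles)
  n <- config$n_frames
  res <- lapply(1:2, function(view) {
    frames <- vector("list", n)
    truths <- vector("list", n)
    for (i in seq_len(n)) {
      r <- render_one_frame(i, view, cameras[[view]], trajectories, config,
                            truth_rows = TRUE,
                            intensity_profiles = intensity_profiles)
      frames[[i]] <- r$frame
      truths[[i]] <- r$truth
    }
    list(seq = frame_sequence(frames, config$frame_rate),
         truth = do.call(rbind, truths))
  })
  truth <- if (length(trajectories))
    merge_truth(res[[1]]$truth, res[[2]]$truth)
  else scene_ground_truth(trajectories, cameras, config)
  list(view1 = res[[1]]$seq, view2 = res[[2]]$seq, truth = truth)
}

merge_truth <- function(t1, t2) {
  out <- data.frame(frame = t1$frame, blob_id = t1$blob_id,
                    x = t1$x, y = t1$y, z = t1$z,
                    u1 = t1$u, v1 = t1$v, u2 = t2$u, v2 = t2$v,
                    in_view1 = t1$in_view, in_view2 = t2$in_view)
  out$isum1_red <- t1$isum_red; out$isum1_green <- t1$isum_green
  out$isum1_blue <- t1$isum_blue
  out$isum2_red <- t2$isum_red; out$isum2_green <- t2$isum_green
  out$isum2_blue <- t2$isum_blue
  out[order(out$frame, out$blob_id), ]
}

check_scene_args <- function(trajectories, cameras, config,
                             intensity_profiles = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(intensity_profiles) &&
      (length(intensity_profiles) != length(trajectories) ||
       !all(vapply(intensity_profiles, length, integer(1)) ==
            config$n_frames)))
    stop_fluotrack("intensity_profiles must hold one length-n_frames vector per blob")
  if (!is.list(cameras) || length(cameras) != 2L ||
      !all(vapply(cameras, inherits, logical(1), "camera_model")))
    stop_fluotrack("exactly two camera_model objects are required")
  if (!is.list(trajectories))
    stop_fluotrack("trajectories must be a list of n x 3 matrices (one per blob)")
  ok <- vapply(trajectories, function(tr)
    is.matrix(tr) && nrow(tr) == config$n_frames && ncol(tr) == 3L,
    logical(1))
  if (!all(ok))
    stop_fluotrack("each trajectory must be an n_frames x 3 matrix")
}

#' Streaming frame source for one rendered view
#'
#' Like [render_sequence()] but frames are produced on demand, so long
#' scenes can feed [analyze_view()] or [run_batch()] in constant memory.
#'
#' @inheritParams render_sequence
#' @param view View to render (1 or 2).
#' @return A frame source usable wherever a frame sequence is accepted.
#' @export
scene_frame_source <- function(trajectories, cameras, config, view,
                               intensity_profiles = NULL) {
  check_scene_args(trajectories, cameras, config, intensity_profiles)
  new_frame_source(config$n_frames, config$frame_rate,
                   function(i) render_one_frame(i, view, cameras[[view]],
                                                trajectories, config,
                                                intensity_profiles =
                                                  intensity_profiles),
                   c(config$image_height, config$image_width, 3L))
}

#' Ground truth table of a scene without rendering pixels
#'
#' @inheritParams render_sequence
#' @return Data frame: frame, blob_id, true 3D position, projected pixel
#'   per view (0-based u, v) and in-view flags.
#' @export
scene_ground_truth <- function(trajectories, cameras, config) {
  check_scene_args(trajectories, cameras, config)
  H <- config$image_height; W <- config$image_width
  if (!length(trajectories))
    return(data.frame(frame = integer(), blob_id = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      u1 = numeric(), v1 = numeric(),
                      u2 = numeric(), v2 = numeric(),
                      in_view1 = logical(), in_view2 = logical()))
  rows <- lapply(seq_along(trajectories), function(b) {
    X <- trajectories[[b]]
    uv1 <- project_point(cameras[[1]], X)
    uv2 <- project_point(cameras[[2]], X)
    data.frame(frame = seq_len(config$n_frames), blob_id = b,
               x = X[, 1], y = X[, 2], z = X[, 3],
               u1 = uv1[, 1], v1 = uv1[, 2], u2 = uv2[, 1], v2 = uv2[, 2],
               in_view1 = uv1[, 1] >= 0 & uv1[, 1] <= W - 1 &
                          uv1[, 2] >= 0 & uv1[, 2] <= H - 1,
               in_view2 = uv2[, 1] >= 0 & uv2[, 1] <= W - 1 &
                          uv2[, 2] >= 0 & uv2[, 2] <= H - 1)
  })
  out <- do.call(rbind, rows)
  out[order(out$frame, out$blob_id), ]
}

#' Write a complete two-view fixture to disk
#'
#' Streams the rendered scene to `dir` as per-view directories of
#' numbered 8-bit RGB PNG frames, one plain-text 3x4 projection-matrix
#' file per camera, and a ground-truth CSV (columns frame, blob_id, x, y,
#' z, u1, v1, u2, v2, in_view1, in_view2). Frames are rendered on demand,
#' so arbitrarily long fixtures use constant memory.
#'
#' @param trajectories,cameras,config As for [render_sequence()].
#' @param dir Output directory.
#' @return Invisibly, a list of the written paths.
#' @export
write_scene_fixture <- function(trajectories, cameras, config, dir) {
  check_scene_args(trajectories, cameras, config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(view1 = file.path(dir, "view1"),
                view2 = file.path(dir, "view2"),
                matrix1 = file.path(dir, "camera1.txt"),
                matrix2 = file.path(dir, "camera2.txt"),
                truth = file.path(dir, "ground_truth.csv"))
  for (view in 1:2) {
    vdir <- paths[[view]]
    dir.create(vdir, showWarnings = FALSE)
    for (i in seq_len(config$n_frames)) {
      fr <- render_one_frame(i, view, cameras[[view]], trajectories, config)
      write_frame_png(fr, file.path(vdir, sprintf("frame_%06d.png", i)))
    }
    write_projection_matrix(cameras[[view]], paths[[paste0("matrix", view)]])
  }
  truth <- scene_ground_truth(trajectories, cameras, config)
  write.csv(truth, paths$truth, row.names = FALSE)
  invisible(paths)
}
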