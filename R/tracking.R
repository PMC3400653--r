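#' Pair single-animal detections across two views
#'
#' 3D reconstruction needs exactly one detection in each synchronized
#' view. Frames where either view has no retained component (animal
#' hidden from that camera) or more than one (several animals, or a split
#' silhouette) are skipped and tallied by reason; cross-view
#' correspondence for multiple identical animals is not attempted.
#'
#' @param view1_obs,view2_obs Data frames of per-frame observations with
#'   at least columns `frame`, `centroid_row`, `centroid_col` (1-based
#'   pixel coordinates as produced by [label_components()]).
#' @return List with `pairs` (data frame: frame, u1, v1, u2, v2 in
#'   0-based pixel convention) and `skipped`, a named integer vector of
#'   skip counts by reason.
#' @export
pair_observations <- function(view1_obs, view2_obs) {
  need <- c("frame", "centroid_row", "centroid_col")
  if (!all(need %in% names(view1_obs)) || !all(need %in% names(view2_obs)))
    stop_fluotrack("observations need columns %s", paste(need, collapse = ", "))
  frames <- sort(union(view1_obs$frame, view2_obs$frame))
  n1 <- table(factor(view1_obs$frame, levels = frames))
  n2 <- table(factor(view2_obs$frame, levels = frames))
  skipped <- c("missing view 1" = 0L, "missing view 2" = 0L,
               "multiple view 1" = 0L, "multiple view 2" = 0L)
  keep <- logical(length(frames))
  for (i in seq_along(frames)) {
    a <- n1[i]; b <- n2[i]
    if (a == 1L && b == 1L) { keep[i] <- TRUE; next }
    if (a == 0L) skipped["missing view 1"] <- skipped["missing view 1"] + 1L
    if (b == 0L) skipped["missing view 2"] <- skipped["missing view 2"] + 1L
    if (a > 1L) skipped["multiple view 1"] <- skipped["multiple view 1"] + 1L
    if (b > 1L) skipped["multiple view 2"] <- skipped["multiple view 2"] + 1L
  }
  fk <- frames[keep]
  o1 <- view1_obs[match(fk, view1_obs$frame), ]
  o2 <- view2_obs[match(fk, view2_obs$frame), ]
  pairs <- data.frame(frame = fk,
                      u1 = o1$centroid_col - 1, v1 = o1$centroid_row - 1,
                      u2 = o2$centroid_col - 1, v2 = o2$centroid_row - 1)
  list(pairs = pairs, skipped = skipped)
}

#' Reconstruct a 3D trajectory from paired 2D observations
#'
#' Back-projects each paired centroid through its camera and intersects
#' the two viewing rays by midpoint triangulation. The closest-approach
#' distance of the rays is kept per point as the `gap` diagnostic: large
#' gaps indicate calibration or measurement error, and users can filter
#' on it. Pairs with degenerate (near-parallel) ray geometry are dropped
#' and counted in attribute `n_degenerate`.
#'
#' @param pairs Data frame with columns frame, u1, v1, u2, v2 (0-based
#'   pixels), e.g. from [pair_observations()].
#' @param cam1,cam2 [camera_model()] objects for views 1 and 2.
#' @param frame_rate Frames per second, carried for motion statistics.
#' @return A `trajectory3d`: data frame (frame, x, y, z, gap) with
#'   attributes `frame_rate` and `n_degenerate`.
#' @export
reconstruct_trajectory <- function(pairs, cam1, cam2, frame_rate = 30) {
  if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$pairs))
    pairs <- pairs$pairs
  stopifnot(inherits(cam1, "camera_model"), inherits(cam2, "camera_model"))
  n <- nrow(pairs)
  out <- vector("list", n)
  dropped <- 0L
  for (i in seq_len(n)) {
    r1 <- backproject_pixel(cam1, c(pairs$u1[i], pairs$v1[i]))
    r2 <- backproject_pixel(cam2, c(pairs$u2[i], pairs$v2[i]))
    tri <- tryCatch(triangulate_midpoint(r1, r2), error = function(e) NULL)
    if (is.null(tri)) { dropped <- dropped + 1L; next }
    out[[i]] <- data.frame(frame = pairs$frame[i], x = tri$point[1],
                           y = tri$point[2], z = tri$point[3],
                           gap = tri$gap)
  }
  track <- do.call(rbind, out)
  if (is.null(track))
    track <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                        z = numeric(), gap = numeric())
  structure(track, frame_rate = frame_rate, n_degenerate = dropped,
            class = c("trajectory3d", "data.frame"))
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d: %d points, frames %s-%s, median gap %.3g>\n",
              nrow(x), if (nrow(x)) min(x$frame) else "-",
              if (nrow(x)) max(x$frame) else "-",
              if (nrow(x)) stats::median(x$gap) else NA))
  invisible(x)
}

#' Plot a 3D trajectory as top and side views
#'
#' @param x A `trajectory3d`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.trajectory3d <- function(x, ...) {
  op <- par(mfrow = c(1, 2), pty = "s")
  on.exit(par(op))
  plot(x$x, x$y, col = "red", pch = 0, cex = 0.5, asp = 1,
       xlab = "x", ylab = "y", main = "Top view", ...)
  plot(x$x, x$z, col = "red", pch = 0, cex = 0.5, asp = 1,
       xlab = "x", ylab = "z", main = "Side view", ...)
  invisible(x)
}

# contiguous segments: split where the frame gap exceeds max_frame_gap
split_segments <- function(frames, max_frame_gap) {
  if (!length(frames)) return(integer(0))
  cumsum(c(1L, diff(frames) > max_frame_gap))
}

#' Speed series along a 3D track
#'
#' Euclidean displacement between consecutive track points divided by
#' their time separation. Pairs separated by more than `max_frame_gap`
#' frames (animal lost by one camera for a while) break the series
#' instead of producing spurious straight-line speeds across the gap.
#'
#' @param track A `trajectory3d` (or data frame with frame, x, y, z).
#' @param frame_rate Frames per second.
#' @param max_frame_gap Largest frame gap still treated as continuous
#'   motion.
#' @return Data frame (frame_from, frame_to, speed) in world units per
#'   second; zero rows when the track has fewer than 2 points.
#' @export
compute_velocity <- function(track, frame_rate = attr(track, "frame_rate"),
                             max_frame_gap = 30) {
  if (is.null(frame_rate)) frame_rate <- 30
  n <- nrow(track)
  if (is.null(n) || n < 2L)
    return(data.frame(frame_from = integer(), frame_to = integer(),
                      speed = numeric()))
  dx <- diff(track$x); dy <- diff(track$y); dz <- diff(track$z)
  g <- diff(track$frame)
  keep <- g <= max_frame_gap
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  data.frame(frame_from = track$frame[-n][keep],
             frame_to = track$frame[-1][keep],
             speed = (dist / (g / frame_rate))[keep])
}

#' Heading-change frequency of a 3D track
#'
#' At each interior point of a contiguous track segment the angle between
#' the incoming and outgoing displacement vectors is computed; a
#' direction-change event is counted when it exceeds `angle_threshold`.
#' Frequency is events per second of tracked (contiguous) time.
#' Zero-length displacements carry no direction and are skipped.
#'
#' @inheritParams compute_velocity
#' @param angle_threshold Turn angle in degrees that counts as a heading
#'   change.
#' @return List: `events`, `duration_s` (tracked time), `frequency`
#'   (events/second).
#' @export
heading_change_frequency <- function(track, angle_threshold = 90,
                                     frame_rate = attr(track, "frame_rate"),
                                     max_frame_gap = 30) {
  if (is.null(frame_rate)) frame_rate <- 30
  seg <- split_segments(track$frame, max_frame_gap)
  events <- 0L
  duration <- 0
  for (s in unique(seg)) {
    idx <- which(seg == s)
    if (length(idx) < 2L) next
    duration <- duration +
      (track$frame[max(idx)] - track$frame[min(idx)]) / frame_rate
    if (length(idx) < 3L) next
    P <- as.matrix(track[idx, c("x", "y", "z")])
    V <- diff(P)
    nv <- sqrt(rowSums(V^2))
    for (i in seq_len(nrow(V) - 1)) {
      if (nv[i] == 0 || nv[i + 1] == 0) next
      cosang <- sum(V[i, ] * V[i + 1, ]) / (nv[i] * nv[i + 1])
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (ang > angle_threshold) events <- events + 1L
    }
  }
  list(events = events, duration_s = duration,
       frequency = if (duration > 0) events / duration else NA_real_)
}

#' Motion summary of a 3D track
#'
#' @inheritParams heading_change_frequency
#' @return Object of class `motion_summary`: number of points, mean and
#'   max speed, total path length, heading-change count and frequency,
#'   and per-axis position ranges.
#' @export
motion_summary <- function(track, frame_rate = attr(track, "frame_rate"),
                           angle_threshold = 90, max_frame_gap = 30) {
  if (is.null(frame_rate)) frame_rate <- 30
  vel <- compute_velocity(track, frame_rate, max_frame_gap)
  hc <- heading_change_frequency(track, angle_threshold, frame_rate,
                                 max_frame_gap)
  seg <- split_segments(track$frame, max_frame_gap)
  path <- 0
  for (s in unique(seg)) {
    idx <- which(seg == s)
    if (length(idx) < 2L) next
    P <- as.matrix(track[idx, c("x", "y", "z")])
    path <- path + sum(sqrt(rowSums(diff(P)^2)))
  }
  rng <- function(v) if (length(v)) range(v) else c(NA_real_, NA_real_)
  structure(list(n_points = nrow(track),
                 mean_speed = if (nrow(vel)) mean(vel$speed) else NA_real_,
                 max_speed = if (nrow(vel)) max(vel$speed) else NA_real_,
                 path_length = path,
                 heading_changes = hc$events,
                 heading_change_freq = hc$frequency,
                 range_x = rng(track$x), range_y = rng(track$y),
                 range_z = rng(track$z)),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf(paste0("<motion_summary: %d points; mean speed %.4g, path %.4g;",
                     " %d heading changes (%.4g /s)>\n"),
              x$n_points, x$mean_speed, x$path_length, x$heading_changes,
              x$heading_change_freq))
  invisible(x)
}
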