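#' Per-pixel running-Gaussian background model
#'
#' The background of a static dark-field view is modelled independently
#' at each pixel by a running Gaussian: a per-pixel mean `mu` (and,
#' optionally, variance, kept as instrumentation only) updated by a
#' selective exponential rule with adaptation rate `alpha`. A pixel of
#' the current frame is classified foreground when its detection-channel
#' intensity deviates from `mu` by more than the empirical threshold `T`;
#' only background pixels update the model, so an animal parked over a
#' pixel never bleeds into it.
#'
#' @param mean_image `H x W` numeric matrix of per-pixel means (levels).
#' @param alpha Adaptation rate in `[0, 1]`: 0 freezes the background, 1
#'   replaces it with each frame.
#' @param threshold Classification threshold `T` in levels (> 0);
#'   empirical, tuned per lighting setup and then held fixed across an
#'   experiment.
#' @param channel Detection channel, one of `"red"`, `"green"`, `"blue"`
#'   (green for GFP reporters).
#' @param track_variance Track a per-pixel running variance alongside the
#'   mean (diagnostic only; it never enters classification).
#' @param frames_seen Frames incorporated so far.
#' @return Object of class `background_model`.
#' @export
background_model <- function(mean_image, alpha = 0.05, threshold = 40,
                             channel = "green", track_variance = FALSE,
                             frames_seen = 0L) {
  if (!is.matrix(mean_image) || !is.numeric(mean_image))
    stop_fluotrack("mean_image must be a numeric matrix")
  if (alpha < 0 || alpha > 1) stop_fluotrack("alpha must be in [0, 1]")
  if (threshold <= 0) stop_fluotrack("threshold must be positive")
  if (min(mean_image) < 0 || max(mean_image) > 255)
    stop_fluotrack("mean_image values must lie in [0, 255]")
  structure(list(mean_image = mean_image,
                 variance_image = if (track_variance)
                   matrix(0, nrow(mean_image), ncol(mean_image)),
                 alpha = alpha, threshold = threshold,
                 channel = match.arg(channel, .CHANNELS),
                 frames_seen = as.integer(frames_seen)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model: %dx%d px, channel %s, alpha %.3g, T %.3g, %d frames seen>\n",
              nrow(x$mean_image), ncol(x$mean_image), x$channel,
              x$alpha, x$threshold, x$frames_seen))
  invisible(x)
}

# evenly spaced sample indices including first and last; at least 2
background_sample_indices <- function(n_frames, sample_fraction) {
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop_fluotrack("sample_fraction must be in (0, 1]")
  k <- max(ceiling(sample_fraction * n_frames), 2L)
  k <- min(k, n_frames)
  unique(round(seq(1, n_frames, length.out = k)))
}

#' Initialize the background from evenly sampled frames
#'
#' Rather than bootstrapping from the first frame, a small fraction of
#' the whole recording (1% by default) is sampled at even index
#' intervals, first and last frames included, and averaged per pixel on
#' the detection channel. This gives a clean initial model even when
#' animals are present in every frame, since each sits at any given pixel
#' in only a few of the widely spaced samples.
#'
#' @param frames A [frame_sequence()], list of frames, frame directory,
#'   or internal frame source.
#' @param sample_fraction Fraction of frames to sample, in `(0, 1]`; at
#'   least 2 frames are always used.
#' @inheritParams background_model
#' @return A [background_model()] with `frames_seen` set to the number of
#'   frames sampled.
#' @export
initialize_background <- function(frames, sample_fraction = 0.01,
                                  alpha = 0.05, threshold = 40,
                                  channel = "green",
                                  track_variance = FALSE) {
  src <- open_frame_source(frames)
  if (src$n < 1L) stop_fluotrack("cannot initialize from an empty sequence")
  idx <- background_sample_indices(src$n, sample_fraction)
  ch <- channel_index(channel)
  acc <- NULL
  for (i in idx) {
    f <- src$get(i)[, , ch]
    acc <- if (is.null(acc)) f else acc + f
  }
  background_model(acc / length(idx), alpha = alpha, threshold = threshold,
                   channel = channel, track_variance = track_variance,
                   frames_seen = length(idx))
}

#' Classify a frame against the background model
#'
#' Marks a pixel foreground when `|I - mu| > T` on the detection channel.
#' Pure: the model is not modified.
#'
#' @param frame `H x W x 3` integer frame.
#' @param model A [background_model()].
#' @param frame_index Index recorded on the returned mask.
#' @return A binary change mask: `H x W` logical matrix (TRUE =
#'   foreground) with attributes `frame_index` and class `change_mask`.
#' @export
classify_frame <- function(frame, model, frame_index = NA_integer_) {
  stopifnot(inherits(model, "background_model"))
  ch <- channel_index(model$channel)
  if (!identical(dim(frame)[1:2], dim(model$mean_image)))
    stop_fluotrack("frame dimensions %s do not match model %s",
                   paste(dim(frame)[1:2], collapse = "x"),
                   paste(dim(model$mean_image), collapse = "x"))
  mask <- abs(frame[, , ch] - model$mean_image) > model$threshold
  new_change_mask(mask, frame_index)
}

new_change_mask <- function(mask, frame_index = NA_integer_) {
  structure(mask, frame_index = as.integer(frame_index),
            class = c("change_mask", class(mask)))
}

#' Selectively update the background with a classified frame
#'
#' Background pixels move toward the current frame,
#' `mu <- (1 - alpha) * mu + alpha * I`; foreground pixels are left
#' untouched, so detected animals never drag the model toward their own
#' intensity. If variance is tracked it follows the same selective
#' exponential rule around the updated mean.
#'
#' @param model A [background_model()].
#' @param frame The frame the mask was computed from.
#' @param mask The [classify_frame()] output for `frame`.
#' @return The updated `background_model` (`frames_seen` incremented).
#' @export
update_background <- function(model, frame, mask) {
  stopifnot(inherits(model, "background_model"))
  if (!identical(dim(frame)[1:2], dim(model$mean_image)) ||
      !identical(dim(mask), dim(model$mean_image)))
    stop_fluotrack("frame/mask dimensions do not match the model")
  ch <- channel_index(model$channel)
  I <- frame[, , ch]
  bg <- !mask
  a <- model$alpha
  model$mean_image[bg] <- (1 - a) * model$mean_image[bg] + a * I[bg]
  if (!is.null(model$variance_image)) {
    dev2 <- (I[bg] - model$mean_image[bg])^2
    model$variance_image[bg] <- (1 - a) * model$variance_image[bg] + a * dev2
  }
  model$frames_seen <- model$frames_seen + 1L
  model
}
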