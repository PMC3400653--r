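#' Default intensity bin edges
#'
#' Equal-width quartiles of the 8-bit range: bins `[0,64)`, `[64,128)`,
#' `[128,192)`, `[192,256)`, of increasing intensity. In practice
#' autofluorescence and residual background fall almost entirely in bin
#' 1, while genuine reporter signal populates bins 3--4, which is what
#' makes the binned summary robust where a plain mean would drown signal
#' confined to a small bright region.
#' @export
default_bin_edges <- c(0, 64, 128, 192, 256)

#' Four-bin intensity histogram of a component
#'
#' Assigns every member pixel of a silhouette to the unique intensity bin
#' containing its value on the requested channel, accumulating both pixel
#' counts and per-bin intensity sums. Counts always partition the
#' component and sums partition its total intensity (exact integer
#' identities).
#'
#' @param frame `H x W x 3` integer frame.
#' @param component A silhouette `component`.
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @param bin_edges 5 ascending levels partitioning `[0, 256)`.
#' @return Object of class `channel_histogram`: `channel`, `bin_edges`,
#'   `counts` (length 4, bins of increasing intensity), `intensity_sums`
#'   (length 4).
#' @export
bin_component_intensities <- function(frame, component, channel = "green",
                                      bin_edges = default_bin_edges) {
  stopifnot(inherits(component, "component"))
  if (length(bin_edges) != 5L || is.unsorted(bin_edges, strictly = TRUE))
    stop_fluotrack("bin_edges must be 5 strictly ascending levels")
  ch <- channel_index(channel)
  px <- component$pixel_coords
  if (min(px) < 1 || max(px[, 1]) > dim(frame)[1] ||
      max(px[, 2]) > dim(frame)[2])
    stop_fluotrack("component pixel outside frame bounds")
  I <- frame[cbind(px[, 1], px[, 2], ch)]
  bins <- findInterval(I, bin_edges, rightmost.closed = FALSE)
  if (any(bins < 1 | bins > 4))
    stop_fluotrack("pixel intensity outside the binned range [%g, %g)",
                   bin_edges[1], bin_edges[5])
  structure(list(channel = match.arg(channel, .CHANNELS),
                 bin_edges = bin_edges,
                 counts = tabulate(bins, nbins = 4L),
                 intensity_sums = as.numeric(
                   vapply(1:4, function(b) sum(I[bins == b]), numeric(1)))),
            class = "channel_histogram")
}

#' @export
print.channel_histogram <- function(x, ...) {
  cat(sprintf("<channel_histogram %s: counts %s; sums %s>\n", x$channel,
              paste(x$counts, collapse = "/"),
              paste(signif(x$intensity_sums, 4), collapse = "/")))
  invisible(x)
}

#' Select the reporting bin set across samples
#'
#' To compare relative fluorescence across samples, the highest intensity
#' bin populated in every sample is used; if the top bin is empty for
#' some sample, the next lower bin is added, and so on. The result is a
#' contiguous, top-anchored bin set (`4`, then `c(3, 4)`, ...).
#'
#' @param histograms List of `channel_histogram`s, one per sample, all on
#'   the same channel.
#' @return Integer vector of selected bins, ascending.
#' @export
select_reporting_bin <- function(histograms) {
  if (!length(histograms))
    stop_fluotrack("need at least one sample histogram")
  stopifnot(all(vapply(histograms, inherits, logical(1),
                       "channel_histogram")))
  chans <- vapply(histograms, `[[`, character(1), "channel")
  if (length(unique(chans)) != 1L)
    stop_fluotrack("all sample histograms must be on the same channel")
  totals <- vapply(histograms, function(h) sum(h$counts), numeric(1))
  if (any(totals == 0))
    stop_fluotrack("sample %d has zero pixels: no valid bin set",
                   which(totals == 0)[1])
  for (lo in 4:1) {
    bins <- lo:4
    ok <- vapply(histograms,
                 function(h) sum(h$counts[bins]) > 0, logical(1))
    if (all(ok)) return(sort(bins))
  }
}

#' Average a per-frame series into per-minute values
#'
#' Arithmetic mean over consecutive blocks of `60 * frame_rate` frames; a
#' trailing partial minute averages the frames it has. `NA` entries
#' (frames deliberately skipped upstream) are dropped from their block's
#' mean; a block that is all-`NA` yields `NA`.
#'
#' @param per_frame_values Numeric series, one value per frame.
#' @param frame_rate Frames per second (> 0; may be fractional).
#' @return Numeric per-minute series of length
#'   `ceiling(n / (60 * frame_rate))`.
#' @export
aggregate_per_minute <- function(per_frame_values, frame_rate) {
  if (frame_rate <= 0) stop_fluotrack("frame_rate must be positive")
  n <- length(per_frame_values)
  if (!n) return(numeric(0))
  block <- 60 * frame_rate
  minute <- floor((seq_len(n) - 1) / block) + 1
  as.numeric(tapply(per_frame_values, minute,
                    function(v) mean(v, na.rm = TRUE)))
}

#' LOESS smoothing of a fluorescence series
#'
#' Tricube-weighted local polynomial regression (span 0.1, degree 2 by
#' default) evaluated at every input index, computed exactly
#' (`surface = "direct"`, no robustness iterations).
#'
#' @param series Numeric series (e.g. per-minute fluorescence).
#' @param span Neighbourhood fraction in `(0, 1]`; each local fit uses
#'   the `floor(span * n)` nearest points.
#' @param degree Local polynomial degree (0, 1 or 2).
#' @return Smoothed numeric series, same length as the input.
#' @export
loess_smooth <- function(series, span = 0.1, degree = 2) {
  n <- length(series)
  if (!degree %in% 0:2) stop_fluotrack("degree must be 0, 1 or 2")
  if (span <= 0 || span > 1) stop_fluotrack("span must be in (0, 1]")
  min_n <- ceiling((degree + 2) / span)
  if (floor(span * n) < degree + 2)
    stop_fluotrack("series too short for loess: need at least %d points at span %g, degree %d (got %d)",
                   min_n, span, degree, n)
  x <- seq_len(n)
  fit <- stats::loess(series ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, x))
}

#' Detect induction onset in a smoothed per-minute series
#'
#' Convenience readout of the induction time that is otherwise judged by
#' eye from the smoothed plot: onset is the first minute at which the
#' smoothed value exceeds baseline mean + `k` baseline SD and stays above
#' for at least `hold` consecutive minutes.
#'
#' @param smoothed Smoothed per-minute series (see [loess_smooth()]).
#' @param baseline_minutes Number of leading minutes treated as baseline;
#'   must be shorter than the series.
#' @param k Threshold multiplier on the baseline SD.
#' @param hold Minimum consecutive minutes above threshold.
#' @return Onset minute (1-based index into the series), or `NA` if the
#'   series never rises and holds.
#' @export
detect_onset <- function(smoothed, baseline_minutes, k = 3, hold = 10) {
  n <- length(smoothed)
  if (baseline_minutes >= n)
    stop_fluotrack("baseline window must be shorter than the series")
  base <- smoothed[seq_len(baseline_minutes)]
  thr <- mean(base) + k * stats::sd(base)
  above <- smoothed > thr
  run <- 0L
  for (t in (baseline_minutes + 1):n) {
    run <- if (above[t]) run + 1L else 0L
    if (run >= hold) return(t - hold + 1L)
  }
  NA_integer_
}
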