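#' Frame sequences
#'
#' A frame is an `H x W x 3` integer array of 8-bit levels (0--255, RGB).
#' A frame sequence is an ordered list of equally sized frames plus the
#' frame rate, the unit of video input for the whole pipeline.
#'
#' @param frames List of `H x W x 3` integer arrays with identical
#'   dimensions.
#' @param frame_rate Frames per second.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate = 30) {
  if (!length(frames)) stop_fluotrack("frame sequence is empty")
  dims <- lapply(frames, dim)
  d1 <- dims[[1]]
  if (length(d1) != 3L || d1[3] != 3L)
    stop_fluotrack("frames must be H x W x 3 arrays")
  same <- vapply(dims, function(d) identical(d, d1), logical(1))
  if (!all(same))
    stop_fluotrack("inconsistent frame sizes: frame %d is %s, expected %s",
                   which(!same)[1],
                   paste(dims[[which(!same)[1]]], collapse = "x"),
                   paste(d1, collapse = "x"))
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence: %d frames, %dx%d px, %.4g fps>\n",
              length(x$frames), d[1], d[2], x$frame_rate))
  invisible(x)
}

#' Read a directory of image frames
#'
#' Reads a lexicographically ordered directory of 8-bit PNG frames into a
#' [frame_sequence()].
#'
#' @param source Directory containing `.png` frames.
#' @param frame_rate Frames per second of the recording.
#' @return A `frame_sequence`.
#' @export
read_frames <- function(source, frame_rate = 30) {
  src <- open_frame_source(source, frame_rate)
  frame_sequence(lapply(seq_len(src$n), src$get), frame_rate)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param frames A `frame_sequence` or list of frames.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix; frames are written as
#'   `<prefix>_000001.png`, ...
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames)) write_frame_png(frames[[i]], paths[i])
  invisible(paths)
}

write_frame_png <- function(frame, path) {
  png::writePNG(frame / 255, path)
}

read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  arr <- array(as.integer(round(img * 255)), dim(img))
  arr
}

# --- streaming frame sources -------------------------------------------
#
# A frame source is an internal protocol: list(n, frame_rate, get(i), dim).
# It lets the pipeline stream long recordings (directories) and synthetic
# scenes without materialising every frame in memory.

open_frame_source <- function(source, frame_rate = 30) {
  if (inherits(source, "frame_source")) return(source)
  if (inherits(source, "frame_sequence")) {
    frames <- source$frames
    return(new_frame_source(length(frames), source$frame_rate,
                            function(i) frames[[i]], dim(frames[[1]])))
  }
  if (is.list(source)) {
    if (!length(source)) stop_fluotrack("frame source is an empty sequence")
    return(new_frame_source(length(source), frame_rate,
                            function(i) source[[i]], dim(source[[1]])))
  }
  if (is.character(source) && length(source) == 1L) {
    if (!dir.exists(source))
      stop_fluotrack("frame source '%s' is not a readable directory", source)
    files <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
    if (!length(files))
      stop_fluotrack("no .png frames found in '%s'", source)
    first <- read_frame_png(files[1])
    d <- dim(first)
    get <- function(i) {
      f <- read_frame_png(files[i])
      if (!identical(dim(f), d))
        stop_fluotrack("inconsistent frame sizes: '%s' is %s, expected %s",
                       basename(files[i]), paste(dim(f), collapse = "x"),
                       paste(d, collapse = "x"))
      f
    }
    return(new_frame_source(length(files), frame_rate, get, d))
  }
  stop_fluotrack("cannot interpret frame source of class '%s'",
                 paste(class(source), collapse = "/"))
}

new_frame_source <- function(n, frame_rate, get, dim) {
  structure(list(n = n, frame_rate = frame_rate, get = get, dim = dim),
            class = "frame_source")
}
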