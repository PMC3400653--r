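# shift a logical matrix by (dr, dc), padding with FALSE (out-of-image
# neighbourhood is background by convention)
shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

NEIGH8 <- cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))[-5, ]
NEIGH4 <- NEIGH8[c(2, 4, 5, 7), ]

#' Morphological opening of a change mask
#'
#' Erosion then dilation by a 3x3 square structural element, with the
#' out-of-image neighbourhood treated as background. Opening removes
#' stray foreground speckle smaller than the element while leaving larger
#' silhouettes essentially unchanged (an animal touching the image edge
#' loses its one-pixel rim, consistent with erosion semantics).
#'
#' @param mask Binary `H x W` mask (logical or 0/1).
#' @return Opened mask of the same class/attributes.
#' @export
morphological_open <- function(mask) {
  fi <- attr(mask, "frame_index")
  m <- unclass(mask) > 0
  er <- m
  for (i in seq_len(nrow(NEIGH8)))
    er <- er & shift_mask(m, NEIGH8[i, 1], NEIGH8[i, 2])
  di <- er
  for (i in seq_len(nrow(NEIGH8)))
    di <- di | shift_mask(er, NEIGH8[i, 1], NEIGH8[i, 2])
  new_change_mask(di, if (is.null(fi)) NA_integer_ else fi)
}

#' Connected silhouette components of a binary mask
#'
#' Partitions the foreground pixels into maximal connected components
#' (8-connected by default, so thin diagonal fragments of one animal stay
#' joined), ordered deterministically by bounding-box `(min_row,
#' min_col)`.
#'
#' @param mask Binary `H x W` mask.
#' @param connectivity 8 (default) or 4.
#' @param frame_index,view_id Recorded on each component.
#' @return List of `component` objects; each has `pixel_coords` (n x 2
#'   matrix of 1-based (row, col)), `size`, `bounding_box` (min_row,
#'   min_col, max_row, max_col), `centroid` (row, col), `frame_index`,
#'   `view_id`.
#' @export
label_components <- function(mask, connectivity = 8,
                             frame_index = NA_integer_,
                             view_id = NA_integer_) {
  if (!connectivity %in% c(4, 8))
    stop_fluotrack("connectivity must be 4 or 8")
  if (is.na(frame_index) && !is.null(attr(mask, "frame_index")))
    frame_index <- attr(mask, "frame_index")
  m <- unclass(mask) > 0
  if (!any(m)) return(list())
  neigh <- if (connectivity == 8) NEIGH8 else NEIGH4
  # iterative minimum-label propagation over the foreground
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m] <- seq_len(sum(m))
  big <- .Machine$integer.max
  repeat {
    cur <- ifelse(m, lab, big)
    nxt <- cur
    for (i in seq_len(nrow(neigh))) {
      sh <- shift_int(cur, neigh[i, 1], neigh[i, 2], big)
      nxt <- pmin(nxt, sh)
    }
    nxt[!m] <- big
    if (identical(nxt[m], lab[m])) break
    lab[m] <- nxt[m]
  }
  ids <- lab[m]
  rc <- which(m, arr.ind = TRUE)
  split_idx <- split(seq_len(nrow(rc)), ids)
  comps <- lapply(split_idx, function(ii) {
    px <- rc[ii, , drop = FALSE]
    new_component(px, frame_index, view_id)
  })
  bb <- t(vapply(comps, function(co) co$bounding_box[1:2], numeric(2)))
  comps <- comps[order(bb[, 1], bb[, 2])]
  names(comps) <- NULL
  comps
}

shift_int <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

new_component <- function(pixel_coords, frame_index = NA_integer_,
                          view_id = NA_integer_) {
  px <- matrix(as.integer(pixel_coords), ncol = 2,
               dimnames = list(NULL, c("row", "col")))
  structure(list(pixel_coords = px, size = nrow(px),
                 bounding_box = c(min_row = min(px[, 1]),
                                  min_col = min(px[, 2]),
                                  max_row = max(px[, 1]),
                                  max_col = max(px[, 2])),
                 centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
                 frame_index = as.integer(frame_index),
                 view_id = as.integer(view_id)),
            class = "component")
}

#' @export
print.component <- function(x, ...) {
  cat(sprintf("<component: %d px, centroid (%.2f, %.2f), frame %s, view %s>\n",
              x$size, x$centroid[1], x$centroid[2],
              as.character(x$frame_index), as.character(x$view_id)))
  invisible(x)
}

#' Filter components by size
#'
#' Drops components smaller than `min_size` pixels ("smaller than" is
#' strict: a component of exactly `min_size` pixels is kept). Removes
#' residual speckle that survives opening, and dim partial silhouettes.
#'
#' @param components List of components from [label_components()].
#' @param min_size Minimum size in pixels (>= 0).
#' @return Filtered list, input order preserved.
#' @export
filter_components <- function(components, min_size) {
  if (min_size < 0) stop_fluotrack("min_size must be >= 0")
  components[vapply(components, function(co) co$size >= min_size,
                    logical(1))]
}

#' Centroid of a silhouette component
#'
#' Unweighted arithmetic mean of the member pixel coordinates: the
#' silhouette is binary, so its center of mass is geometric.
#'
#' @param component A `component`.
#' @return Length-2 numeric `(row, col)`, real-valued pixels.
#' @export
component_centroid <- function(component) {
  stopifnot(inherits(component, "component"), component$size >= 1)
  c(row = mean(component$pixel_coords[, 1]),
    col = mean(component$pixel_coords[, 2]))
}
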