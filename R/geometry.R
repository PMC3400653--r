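#' Camera model from a 3x4 projection matrix
#'
#' A pinhole camera is represented by its 3x4 projection matrix `P`,
#' defined up to scale, mapping homogeneous world points `[X; 1]` to
#' homogeneous pixels `s * [u; v; 1]`. The optical center `C` is the
#' unique world point annihilated by `P` and is derived from its right
#' null space. Pixel convention: `u` = column, `v` = row, origin at the
#' top-left corner, 0-based.
#'
#' @param P Numeric 3x4 matrix.
#' @param view_id Optional identifier for the view (1 or 2).
#' @return Object of class `camera_model` with elements `P` (normalized to
#'   unit Frobenius norm), `center` (length-3 optical center) and
#'   `view_id`.
#' @export
camera_model <- function(P, view_id = NA_integer_) {
  P <- as.matrix(P)
  if (!is.numeric(P) || !identical(dim(P), c(3L, 4L)))
    stop_fluotrack("projection matrix must be numeric 3x4")
  if (any(!is.finite(P)))
    stop_fluotrack("projection matrix contains non-finite values")
  M <- P[, 1:3]
  if (qr(M)$rank < 3L)
    stop_fluotrack("left 3x3 block of the projection matrix is rank-deficient")
  P <- P / sqrt(sum(P^2))
  v <- svd(P, nu = 0, nv = 4)$v[, 4]
  if (abs(v[4]) < 1e-12 * sqrt(sum(v^2)))
    stop_fluotrack("camera center is at infinity (null vector has zero last coordinate)")
  structure(list(P = P, center = v[1:3] / v[4], view_id = view_id),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model view %s; optical center (%.4g, %.4g, %.4g)>\n",
              as.character(x$view_id), x$center[1], x$center[2], x$center[3]))
  print(signif(x$P, 4))
  invisible(x)
}

#' Compose a camera from intrinsic and extrinsic parameters
#'
#' Builds the projection matrix `K [R | -R C]` from a focal length (in
#' pixels), principal point `(u0, v0)`, world-to-camera rotation and
#' optical center.
#'
#' @param focal_length Focal length in pixels (> 0).
#' @param principal_point Length-2 numeric, `(u0, v0)` in pixels.
#' @param rotation 3x3 orthonormal matrix; rows are the camera right, down
#'   and forward axes expressed in world coordinates.
#' @param center Length-3 optical center in world units.
#' @param view_id Optional view identifier.
#' @return A [camera_model()]. The unnormalized intrinsics and extrinsics
#'   are retained in attributes `K`, `R` for scene plumbing.
#' @export
make_camera <- function(focal_length, principal_point, rotation, center,
                        view_id = NA_integer_) {
  if (!is.numeric(focal_length) || length(focal_length) != 1L ||
      focal_length <= 0)
    stop_fluotrack("focal_length must be a positive scalar")
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop_fluotrack("rotation must be 3x3 orthonormal (tolerance 1e-9)")
  stopifnot(length(principal_point) == 2L, length(center) == 3L)
  K <- matrix(c(focal_length, 0, 0,
                0, focal_length, 0,
                principal_point[1], principal_point[2], 1), 3, 3)
  P <- K %*% cbind(rotation, -rotation %*% center)
  cam <- camera_model(P, view_id)
  attr(cam, "K") <- K
  attr(cam, "R") <- rotation
  cam
}

#' Read a projection matrix from a plain-text file
#'
#' The file holds 3 rows x 4 whitespace-separated reals; lines starting
#' with `#` are comments. Pixel convention: `u` = column, `v` = row,
#' 0-based, origin top-left.
#'
#' @param path Path to the matrix file.
#' @param view_id Optional view identifier.
#' @return A [camera_model()].
#' @export
load_projection_matrix <- function(path, view_id = NA_integer_) {
  if (!file.exists(path))
    stop_fluotrack("projection matrix file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))))
  if (length(vals) != 12L || any(is.na(vals)))
    stop_fluotrack("malformed projection matrix file '%s': expected 12 numbers in 3 rows of 4, got %d",
                   path, sum(!is.na(vals)))
  camera_model(matrix(vals, 3, 4, byrow = TRUE), view_id)
}

#' Write a camera's projection matrix to a plain-text file
#'
#' @param camera A [camera_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_projection_matrix <- function(camera, path) {
  stopifnot(inherits(camera, "camera_model"))
  rows <- apply(camera$P, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c("# 3x4 camera projection matrix (row-major).",
               "# Pixel convention: u = column, v = row, 0-based, origin top-left.",
               rows), path)
  invisible(path)
}

#' Project world points to pixels
#'
#' Applies `s [u; v; 1] = P [X; 1]` and dehomogenizes.
#'
#' @param camera A [camera_model()].
#' @param X Length-3 point or n x 3 matrix of world points.
#' @return Length-2 pixel `(u, v)` or n x 2 matrix.
#' @export
project_point <- function(camera, X) {
  stopifnot(inherits(camera, "camera_model"))
  one <- is.null(dim(X))
  X <- rbind2mat(X)
  h <- camera$P %*% rbind(t(X), 1)
  s <- h[3, ]
  if (any(abs(s) < 1e-12 * sqrt(sum(camera$P^2)) * sqrt(1 + rowSums(X^2))))
    stop_fluotrack("point lies on the camera's principal plane (zero projective scale)")
  out <- cbind(u = h[1, ] / s, v = h[2, ] / s)
  if (one) out[1, ] else out
}

rbind2mat <- function(X) {
  if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
}

#' Back-project a pixel to a viewing ray
#'
#' Returns the 3D ray of all world points imaging to pixel `x`: origin at
#' the optical center, unit direction chosen so points along the ray have
#' positive projective depth and project exactly back to `x`.
#'
#' @param camera A [camera_model()].
#' @param x Length-2 pixel `(u, v)`.
#' @return Object of class `ray3` with elements `origin`, `direction`.
#' @export
backproject_pixel <- function(camera, x) {
  stopifnot(inherits(camera, "camera_model"), length(x) == 2L)
  d <- solve(camera$P[, 1:3], c(x, 1))
  d <- d / sqrt(sum(d^2))
  structure(list(origin = camera$center, direction = d), class = "ray3")
}

#' Midpoint triangulation of two viewing rays
#'
#' Finds the closest points on two skew (or intersecting) 3D lines by
#' solving the 2x2 normal equations of the perpendicularity conditions,
#' and returns the midpoint of the shortest connecting segment together
#' with its length (the "gap", a reconstruction-quality diagnostic: rays
#' from real detections rarely intersect exactly).
#'
#' @param ray1,ray2 Objects of class `ray3`.
#' @return List with `point` (length-3 midpoint) and `gap` (closest
#'   approach distance, world units).
#' @export
triangulate_midpoint <- function(ray1, ray2) {
  stopifnot(inherits(ray1, "ray3"), inherits(ray2, "ray3"))
  d1 <- ray1$direction / sqrt(sum(ray1$direction^2))
  d2 <- ray2$direction / sqrt(sum(ray2$direction^2))
  dd <- sum(d1 * d2)
  sin2 <- max(0, 1 - dd^2)
  if (sqrt(sin2) <= 1e-9)
    stop_fluotrack("degenerate geometry: viewing rays are (near-)parallel")
  b <- ray2$origin - ray1$origin
  # minimize |o1 + t1 d1 - o2 - t2 d2|: normal equations in (t1, t2)
  t1 <- (sum(b * d1) - sum(b * d2) * dd) / sin2
  t2 <- (sum(b * d1) * dd - sum(b * d2)) / sin2
  p1 <- ray1$origin + t1 * d1
  p2 <- ray2$origin + t2 * d2
  list(point = (p1 + p2) / 2, gap = sqrt(sum((p1 - p2)^2)))
}

#' Fit a projection matrix from 3D-2D correspondences
#'
#' Direct linear transform over at least 6 known world-pixel pairs; a
#' fixture-building convenience for constructing calibrated synthetic
#' rigs, not a substitute for checkerboard calibration of real cameras.
#'
#' @param X n x 3 matrix of world points (n >= 6, non-coplanar).
#' @param x n x 2 matrix of the matching pixels.
#' @param view_id Optional view identifier.
#' @return A [camera_model()].
#' @export
fit_projection_matrix <- function(X, x, view_id = NA_integer_) {
  X <- as.matrix(X); x <- as.matrix(x)
  n <- nrow(X)
  if (n < 6L || nrow(x) != n)
    stop_fluotrack("need >= 6 matched 3D-2D correspondences")
  Xh <- cbind(X, 1)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    A[2 * i - 1, ] <- c(Xh[i, ], rep(0, 4), -x[i, 1] * Xh[i, ])
    A[2 * i, ]     <- c(rep(0, 4), Xh[i, ], -x[i, 2] * Xh[i, ])
  }
  p <- svd(A, nu = 0)$v[, 12]
  camera_model(matrix(p, 3, 4, byrow = TRUE), view_id)
}
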