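# Independent brute-force oracles. These are deliberately naive,
# definition-level implementations kept separate from the package code
# paths they check.

# random binary mask
random_mask <- function(h, w, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# morphological opening straight from the set definitions:
# erosion = every 3x3 neighbour (out-of-image = background) foreground,
# dilation = any 3x3 neighbour of the eroded set
oracle_open <- function(m) {
  h <- nrow(m); w <- ncol(m)
  at <- function(mm, r, c) r >= 1 && r <= h && c >= 1 && c <= w && mm[r, c]
  er <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1)
      if (!at(m, r + dr, c + dc)) ok <- FALSE
    er[r, c] <- ok
  }
  di <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    any_n <- FALSE
    for (dr in -1:1) for (dc in -1:1)
      if (at(er, r + dr, c + dc)) any_n <- TRUE
    di[r, c] <- any_n
  }
  di
}

# stack-based flood fill over all foreground seeds
oracle_label <- function(m, connectivity = 8) {
  h <- nrow(m); w <- ncol(m)
  neigh <- if (connectivity == 8)
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!m[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(neigh))) {
        r <- p[1] + neigh[k, 1]; c <- p[2] + neigh[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# partitions as canonical lists: sorted integer pixel-index sets, ordered
# by their smallest member
canonical_partition <- function(sets) {
  sets <- lapply(sets, function(s) as.integer(sort(s)))
  unname(sets[order(vapply(sets, min, integer(1)))])
}
partition_sets <- function(lab) {
  idx <- which(lab > 0)
  canonical_partition(split(idx, lab[idx]))
}
components_as_sets <- function(comps, nrow) {
  canonical_partition(lapply(comps, function(co)
    (co$pixel_coords[, 2] - 1L) * nrow + co$pixel_coords[, 1]))
}

# tricube windowed weighted-least-squares smoother, one plain fit per
# evaluation point
oracle_loess <- function(y, span, degree) {
  n <- length(y); x <- seq_len(n)
  q <- floor(span * n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    use <- w > 0
    X <- outer(x[use] - x[i], 0:degree, "^")
    unname(stats::lm.wfit(X, y[use], w[use])$coefficients[1])
  }, numeric(1))
}

# step-by-step extrinsic-then-intrinsic pinhole projection
oracle_project <- function(focal, pp, R, C, X) {
  xc <- as.numeric(R %*% (X - C))
  c(focal * xc[1] / xc[3] + pp[1], focal * xc[2] / xc[3] + pp[2])
}

# random orthonormal rotation via QR with positive determinant
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random camera looking roughly at the origin from a random direction
random_camera <- function(view_id = NA_integer_) {
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  C <- dir * runif(1, 50, 120)
  fwd <- -dir
  up0 <- c(0, 0, 1)
  if (abs(sum(up0 * fwd)) > 0.99) up0 <- c(0, 1, 0)
  down <- -up0
  r2 <- down - sum(down * fwd) * fwd; r2 <- r2 / sqrt(sum(r2^2))
  r1 <- vcross(r2, fwd)
  make_camera(runif(1, 200, 500), runif(2, 100, 200),
              rbind(r1, r2, fwd), C, view_id)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# small quick-to-render scene shared by several tests
small_scene_config <- function(...) {
  args <- utils::modifyList(
    list(image_height = 80, image_width = 100, frame_rate = 30,
         n_frames = 40, noise_sd = 2, random_seed = 7),
    list(...))
  do.call(scene_config, args)
}
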