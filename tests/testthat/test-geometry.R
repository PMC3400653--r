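test_that("projection matrix files load with derived optical center", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "canon.txt")
  writeLines(c("# canonical camera", "1 0 0 0", "0 1 0 0", "0 0 1 0"), p1)
  cam <- load_projection_matrix(p1)
  expect_equal(cam$center, c(0, 0, 0))

  set.seed(41)
  for (r in 1:10) {
    cam0 <- random_camera()
    p <- file.path(dir, sprintf("cam%d.txt", r))
    write_projection_matrix(cam0, p)
    cam <- load_projection_matrix(p, r)
    expect_equal(cam$center, cam0$center, tolerance = 1e-9)
    # null-space identity after unit normalization
    expect_lt(max(abs(cam$P %*% c(cam$center, 1))), 1e-9)
    expect_equal(cam$view_id, r)
  }

  bad <- file.path(dir, "bad.txt")
  writeLines(c("1 2 3", "4 5 6"), bad)
  expect_error(load_projection_matrix(bad), "malformed")
  defic <- file.path(dir, "rank.txt")
  writeLines(c("1 0 0 1", "1 0 0 2", "0 0 1 3"), defic)
  expect_error(load_projection_matrix(defic), "rank-deficient")
  expect_error(load_projection_matrix(file.path(dir, "none.txt")),
               "does not exist")
})

test_that("projection is homogeneous and matches direct arithmetic", {
  cam <- camera_model(cbind(diag(3), 0))
  expect_equal(as.numeric(project_point(cam, c(0, 0, 1))), c(0, 0))

  set.seed(42)
  for (r in 1:15) {
    P <- matrix(rnorm(12), 3, 4)
    if (qr(P[, 1:3])$rank < 3) next
    cam <- camera_model(P)
    lam <- runif(1, 0.1, 9)
    cam2 <- camera_model(lam * P)
    X <- rnorm(3, sd = 10)
    h <- P %*% c(X, 1)
    if (abs(h[3]) < 1e-3) next
    direct <- c(h[1] / h[3], h[2] / h[3])
    expect_equal(as.numeric(project_point(cam, X)), direct,
                 tolerance = 1e-9)
    expect_equal(project_point(cam2, X), project_point(cam, X),
                 tolerance = 1e-9)
  }

  # principal-plane point has zero projective scale
  cam <- camera_model(cbind(diag(3), 0))
  expect_error(project_point(cam, c(1, 1, 0)), "principal plane")
})

test_that("back-projected rays start at the center and re-project exactly", {
  set.seed(43)
  for (r in 1:15) {
    cam <- random_camera()
    x <- runif(2, 0, 300)
    ray <- backproject_pixel(cam, x)
    expect_identical(ray$origin, cam$center)
    expect_equal(sum(ray$direction^2), 1, tolerance = 1e-12)
    for (t in c(0.5, 1, 20))
      expect_equal(as.numeric(project_point(cam, ray$origin + t * ray$direction)),
                   as.numeric(x), tolerance = 1e-9)
    # direction from the two-point line construction oracle:
    # solve P [X;1] = s [x;1] at two scales and join the solutions
    M <- cam$P[, 1:3]; p4 <- cam$P[, 4]
    X1 <- solve(M, 1 * c(x, 1) - p4)
    X2 <- solve(M, 5 * c(x, 1) - p4)
    d <- (X2 - X1) / sqrt(sum((X2 - X1)^2))
    expect_equal(abs(sum(d * ray$direction)), 1, tolerance = 1e-9)
  }
})

test_that("midpoint triangulation solves the two-ray closest-point problem", {
  # intersecting rays recover the common point exactly
  X <- c(3, -2, 5)
  o1 <- c(10, 0, 0); o2 <- c(0, 12, -4)
  r1 <- structure(list(origin = o1,
                       direction = (X - o1) / sqrt(sum((X - o1)^2))),
                  class = "ray3")
  r2 <- structure(list(origin = o2,
                       direction = (X - o2) / sqrt(sum((X - o2)^2))),
                  class = "ray3")
  tri <- triangulate_midpoint(r1, r2)
  expect_equal(tri$point, X, tolerance = 1e-12)
  expect_equal(tri$gap, 0, tolerance = 1e-12)

  # hand-constructed skew pair with known common perpendicular
  rx <- structure(list(origin = c(0, 0, 0), direction = c(1, 0, 0)),
                  class = "ray3")
  ry <- structure(list(origin = c(0, 0, 2), direction = c(0, 1, 0)),
                  class = "ray3")
  tri <- triangulate_midpoint(rx, ry)
  expect_equal(tri$point, c(0, 0, 1))
  expect_equal(tri$gap, 2)

  par1 <- structure(list(origin = c(0, 0, 0), direction = c(1, 0, 0)),
                    class = "ray3")
  par2 <- structure(list(origin = c(0, 1, 0), direction = c(-1, 0, 0)),
                    class = "ray3")
  expect_error(triangulate_midpoint(par1, par2), "parallel")
})

test_that("project/backproject/triangulate round-trips random points", {
  set.seed(44)
  for (r in 1:20) {
    cam1 <- random_camera(1L); cam2 <- random_camera(2L)
    X <- rnorm(3, sd = 5)
    tri <- triangulate_midpoint(
      backproject_pixel(cam1, project_point(cam1, X)),
      backproject_pixel(cam2, project_point(cam2, X)))
    expect_equal(tri$point, X, tolerance = 1e-8)
    expect_lt(tri$gap, 1e-8)
  }
})

test_that("half-pixel detection noise stays within 1% of chamber diameter", {
  cfg <- scene_config()
  cams <- default_cameras(cfg)
  set.seed(45)
  worst <- 0
  for (r in 1:50) {
    ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, cfg$chamber_radius)
    X <- c(rad * cos(ang), rad * sin(ang),
           runif(1, 0, cfg$chamber_height))
    x1 <- project_point(cams[[1]], X) + runif(2, -0.5, 0.5)
    x2 <- project_point(cams[[2]], X) + runif(2, -0.5, 0.5)
    tri <- triangulate_midpoint(backproject_pixel(cams[[1]], x1),
                                backproject_pixel(cams[[2]], x2))
    worst <- max(worst, sqrt(sum((tri$point - X)^2)))
  }
  expect_lt(worst, 0.01 * 2 * cfg$chamber_radius)
})

test_that("DLT fit recovers a camera from 3D-2D correspondences", {
  set.seed(46)
  cam <- random_camera()
  X <- matrix(rnorm(30, sd = 8), 10, 3)
  x <- project_point(cam, X)
  fit <- fit_projection_matrix(X, x)
  Xt <- matrix(rnorm(15, sd = 8), 5, 3)
  expect_equal(project_point(fit, Xt), project_point(cam, Xt),
               tolerance = 1e-6)
  expect_error(fit_projection_matrix(X[1:4, ], x[1:4, ]), ">= 6")
})
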