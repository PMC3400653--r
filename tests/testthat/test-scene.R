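test_that("make_camera composes intrinsics and extrinsics correctly", {
  cam <- make_camera(1, c(0, 0), diag(3), c(0, 0, 0))
  P <- cam$P / cam$P[1, 1]
  expect_equal(P, cbind(diag(3), 0), tolerance = 1e-12)

  set.seed(101)
  for (r in 1:20) {
    cam <- random_camera()
    # optical center is annihilated by P
    expect_lt(max(abs(cam$P %*% c(cam$center, 1))), 1e-9)
    # projection matches the two-stage transform oracle
    K <- attr(cam, "K"); R <- attr(cam, "R")
    X <- cam$center + as.numeric(t(R) %*% c(rnorm(2), runif(1, 10, 50)))
    expect_equal(as.numeric(project_point(cam, X)),
                 oracle_project(K[1, 1], K[1:2, 3], R, cam$center, X),
                 tolerance = 1e-8)
  }
})

test_that("make_camera rejects bad parameters", {
  expect_error(make_camera(-1, c(0, 0), diag(3), c(0, 0, 0)), "focal")
  bad <- diag(3); bad[1, 2] <- 1e-6
  expect_error(make_camera(1, c(0, 0), bad, c(0, 0, 0)), "orthonormal")
})

test_that("trajectories respect their kind and stay in the chamber", {
  cfg <- small_scene_config()
  st <- make_trajectory("stationary", cfg)
  expect_equal(nrow(st), cfg$n_frames)
  expect_true(all(apply(st, 2, function(v) all(v == v[1]))))

  hx <- make_trajectory("helix", cfg, radius = 5)
  expect_equal(sqrt(hx[, 1]^2 + hx[, 2]^2), rep(5, cfg$n_frames))

  rw1 <- make_trajectory("bounded-random-walk", cfg)
  rw2 <- make_trajectory("bounded-random-walk", cfg)
  expect_identical(rw1, rw2)
  for (tr in list(st, hx, rw1)) {
    expect_true(all(sqrt(tr[, 1]^2 + tr[, 2]^2) <= cfg$chamber_radius))
    expect_true(all(tr[, 3] >= 0 & tr[, 3] <= cfg$chamber_height))
  }
  expect_error(make_trajectory("zigzag", cfg))
})

test_that("rendering matches its analytic photometric model", {
  cfg0 <- scene_config(image_height = 40, image_width = 50, n_frames = 3,
                       noise_sd = 0, background_level = 12,
                       random_seed = 3)
  cams <- default_cameras(cfg0)
  blank <- render_sequence(list(), cams, cfg0)
  expect_true(all(vapply(blank$view1$frames,
                         function(f) all(f == 12L), logical(1))))
  expect_equal(nrow(blank$truth), 0L)

  # noiseless single blob: intensity-weighted centroid of the brightest
  # spot matches the ground-truth projection within half a pixel
  cfg <- small_scene_config(noise_sd = 0)
  cams <- default_cameras(cfg)
  tr <- make_trajectory("stationary", cfg)
  sc <- render_sequence(list(tr), cams, cfg)
  fr <- sc$view1$frames[[1]]
  g <- fr[, , 2] - cfg$background_level
  idx <- which(g > 0, arr.ind = TRUE)
  wgt <- g[g > 0]
  cen <- c(sum(idx[, 1] * wgt), sum(idx[, 2] * wgt)) / sum(wgt)
  truth1 <- sc$truth[sc$truth$frame == 1, ]
  expect_lt(abs(cen[1] - (truth1$v1 + 1)), 0.5)
  expect_lt(abs(cen[2] - (truth1$u1 + 1)), 0.5)

  # ground truth bookkeeping: one row per (frame, blob)
  tr2 <- make_trajectory("helix", cfg)
  sc2 <- render_sequence(list(tr, tr2), cams, cfg)
  expect_equal(nrow(sc2$truth), cfg$n_frames * 2)
  expect_equal(unname(table(sc2$truth$blob_id)),
               rep(cfg$n_frames, 2), ignore_attr = TRUE)
})

test_that("identical configs render bit-identical frame stacks", {
  cfg <- small_scene_config(n_frames = 6)
  cams <- default_cameras(cfg)
  tr <- make_trajectory("bounded-random-walk", cfg)
  a <- render_sequence(list(tr), cams, cfg)
  b <- render_sequence(list(tr), cams, cfg)
  expect_identical(a$view1$frames, b$view1$frames)
  expect_identical(a$view2$frames, b$view2$frames)
  # streaming source agrees with in-memory rendering frame by frame
  srcs <- scene_frame_source(list(tr), cams, cfg, 2)
  expect_identical(lapply(seq_len(cfg$n_frames), srcs$get),
                   b$view2$frames)
})

test_that("scene invariants are enforced at construction", {
  expect_error(scene_config(n_frames = 1), "n_frames")
  expect_error(scene_config(blob_peak_intensity = 15, background_level = 10,
                            noise_sd = 2), "undetectable")
  expect_error(scene_config(chamber_radius = -1), "positive")
  cfg <- small_scene_config(n_frames = 4)
  expect_error(render_sequence(list(make_trajectory("stationary", cfg)),
                               default_cameras(cfg)[1], cfg),
               "two camera")
})

test_that("triangulating ground-truth projections recovers the true path", {
  cfg <- small_scene_config(n_frames = 30)
  cams <- default_cameras(cfg)
  tr <- make_trajectory("bounded-random-walk", cfg)
  gt <- scene_ground_truth(list(tr), cams, cfg)
  err <- vapply(seq_len(nrow(gt)), function(i) {
    r1 <- backproject_pixel(cams[[1]], c(gt$u1[i], gt$v1[i]))
    r2 <- backproject_pixel(cams[[2]], c(gt$u2[i], gt$v2[i]))
    tri <- triangulate_midpoint(r1, r2)
    sqrt(sum((tri$point - c(gt$x[i], gt$y[i], gt$z[i]))^2))
  }, numeric(1))
  expect_lt(max(err), 1e-6)
})

test_that("full detection pipeline recovers a rendered single blob", {
  cfg <- small_scene_config(n_frames = 60)
  cams <- default_cameras(cfg)
  tr <- make_trajectory("helix", cfg)
  gt <- scene_ground_truth(list(tr), cams, cfg)
  # short sequences need a generous initialization sample so the blob's
  # sampled positions are averaged out of the starting background
  av <- lapply(1:2, function(v)
    analyze_view(scene_frame_source(list(tr), cams, cfg, v),
                 config = list(sample_fraction = 0.25), view_id = v))
  for (v in 1:2) {
    inview <- gt$frame[gt[[paste0("in_view", v)]]]
    dets <- av[[v]]$detections
    one_comp <- sum(table(dets$frame[dets$frame %in% inview]) == 1)
    expect_gte(one_comp / length(inview), 0.95)
  }
})

test_that("fixture writer round-trips frames, cameras and truth", {
  cfg <- small_scene_config(n_frames = 5)
  cams <- default_cameras(cfg)
  tr <- make_trajectory("helix", cfg)
  dir <- withr::local_tempdir()
  paths <- write_scene_fixture(list(tr), cams, cfg, dir)
  sc <- render_sequence(list(tr), cams, cfg)
  back <- read_frames(paths$view1, cfg$frame_rate)
  expect_identical(back$frames, sc$view1$frames)
  cam_back <- load_projection_matrix(paths$matrix1, 1L)
  expect_equal(cam_back$center, cams[[1]]$center, tolerance = 1e-9)
  truth <- read.csv(paths$truth)
  expect_equal(nrow(truth), cfg$n_frames)
  expect_equal(truth$u1, sc$truth$u1, tolerance = 1e-10)
})
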