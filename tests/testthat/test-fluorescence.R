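frame_with_pixels <- function(levels, h = 8, w = 8, channel = 2) {
  fr <- array(0L, c(h, w, 3L))
  for (i in seq_along(levels)) fr[i, 1, channel] <- as.integer(levels[i])
  fr
}
column_component <- function(n, h = max(8, n)) {
  m <- matrix(FALSE, h, 8); m[seq_len(n), 1] <- TRUE
  label_components(m)[[1]]
}

test_that("binning assigns pixels to the quartile intensity bins", {
  fr <- frame_with_pixels(rep(0, 5))
  h <- bin_component_intensities(fr, column_component(5))
  expect_equal(h$counts, c(5, 0, 0, 0))
  expect_equal(h$intensity_sums, c(0, 0, 0, 0))

  fr <- frame_with_pixels(c(10, 70, 130, 200))
  h <- bin_component_intensities(fr, column_component(4))
  expect_equal(h$counts, c(1, 1, 1, 1))
  expect_equal(h$intensity_sums, c(10, 70, 130, 200))

  # edge values land in the higher bin (left-closed bins)
  fr <- frame_with_pixels(c(63, 64, 127, 128, 191, 192, 255))
  h <- bin_component_intensities(fr, column_component(7))
  expect_equal(h$counts, c(1, 2, 2, 2))
})

test_that("counts and sums are exact partitions of the component", {
  set.seed(31)
  for (r in 1:50) {
    n <- sample(1:40, 1)
    lv <- sample(0:255, n, TRUE)
    fr <- frame_with_pixels(lv, h = 40)
    co <- column_component(n)
    for (chn in c("red", "green", "blue")) {
      h <- bin_component_intensities(fr, co, chn)
      expect_identical(sum(h$counts), co$size)
      tot <- if (chn == "green") sum(lv) else 0
      expect_equal(sum(h$intensity_sums), tot)
      # per-bin sums bounded by count x bin edges
      for (b in 1:4)
        expect_true(h$intensity_sums[b] >= h$counts[b] * h$bin_edges[b] &&
                    h$intensity_sums[b] <= h$counts[b] * (h$bin_edges[b + 1] - 1))
    }
  }
})

test_that("binning rejects invalid inputs", {
  fr <- frame_with_pixels(1:3)
  co <- column_component(3)
  expect_error(bin_component_intensities(fr, co, bin_edges = c(0, 1, 2)),
               "bin_edges")
  big <- label_components({m <- matrix(FALSE, 8, 8); m[8, 8] <- TRUE; m})[[1]]
  expect_error(bin_component_intensities(fr[1:4, , , drop = FALSE], big),
               "bounds")
})

test_that("reporting bin set is the highest populated in every sample", {
  mk <- function(counts) structure(
    list(channel = "green", bin_edges = default_bin_edges,
         counts = counts, intensity_sums = counts * 10),
    class = "channel_histogram")
  expect_equal(select_reporting_bin(list(mk(c(5, 0, 0, 2)),
                                         mk(c(1, 1, 1, 1)))), 4)
  expect_equal(select_reporting_bin(list(mk(c(5, 0, 3, 0)),
                                         mk(c(1, 1, 1, 1)))), c(3, 4))
  expect_equal(select_reporting_bin(list(mk(c(5, 0, 0, 0)),
                                         mk(c(1, 0, 0, 0)))), 1:4)
  expect_error(select_reporting_bin(list(mk(c(0, 0, 0, 0)))), "zero pixels")
  expect_error(select_reporting_bin(list()), "at least one")
})

test_that("per-minute aggregation averages frame blocks", {
  expect_equal(aggregate_per_minute(rep(7, 300), 2), rep(7, 3))

  # linear ramp over exactly two minutes: block means in closed form
  fr <- 2
  ramp <- seq_len(240)
  expect_equal(aggregate_per_minute(ramp, fr),
               c(mean(1:120), mean(121:240)))

  # 90 s at 30 fps: one full and one partial minute
  expect_length(aggregate_per_minute(seq_len(90 * 30), 30), 2L)
  expect_equal(aggregate_per_minute(numeric(0), 30), numeric(0))
  expect_error(aggregate_per_minute(1:10, 0), "frame_rate")

  # NA frames (skip mode) are dropped from their block's mean
  v <- c(1, NA, 3, rep(NA, 57), rep(5, 60))
  expect_equal(aggregate_per_minute(v, 1), c(2, 5))
})

test_that("loess smoothing reproduces polynomials and matches the WLS oracle", {
  expect_equal(loess_smooth(rep(4.2, 60)), rep(4.2, 60))

  x <- seq_len(50)
  quad <- 3 + 0.5 * x - 0.02 * x^2
  expect_equal(loess_smooth(quad, span = 0.3, degree = 2), quad,
               tolerance = 1e-8)

  set.seed(32)
  y <- cumsum(rnorm(200))
  for (sp in c(0.1, 0.25)) {
    expect_equal(loess_smooth(y, span = sp, degree = 2),
                 oracle_loess(y, sp, 2), tolerance = 1e-6)
    expect_equal(loess_smooth(y, span = sp, degree = 1),
                 oracle_loess(y, sp, 1), tolerance = 1e-6)
  }

  expect_error(loess_smooth(rep(1, 10), span = 0.1), "at least 40")
})

test_that("onset detection finds a held rise above baseline", {
  expect_true(is.na(detect_onset(rep(1, 100), baseline_minutes = 20)))
  expect_error(detect_onset(rep(1, 10), baseline_minutes = 10), "baseline")

  # step function rising at minute 100: onset within the smoothing window
  set.seed(33)
  y <- c(rnorm(99, 0, 0.01), rnorm(101, 10, 0.01))
  sm <- loess_smooth(y, span = 0.1, degree = 2)
  onset <- detect_onset(sm, baseline_minutes = 50, k = 3, hold = 10)
  expect_false(is.na(onset))
  expect_lt(abs(onset - 100), 0.1 * length(y))

  # sigmoid induction with a known rise point
  t <- seq_len(300)
  sig <- 5 / (1 + exp(-(t - 150) / 3)) + rnorm(300, 0, 0.1)
  sm <- loess_smooth(sig, span = 0.1, degree = 2)
  onset <- detect_onset(sm, baseline_minutes = 60, k = 3, hold = 10)
  expect_lt(abs(onset - 150), 0.1 * 300)
})

test_that("a dim component reads zero in the high-intensity bins", {
  set.seed(34)
  lv <- sample(0:60, 20, TRUE)
  fr <- frame_with_pixels(lv, h = 20)
  h <- bin_component_intensities(fr, column_component(20))
  expect_equal(h$counts[2:4], c(0, 0, 0))
  expect_equal(h$intensity_sums[2:4], c(0, 0, 0))
})
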