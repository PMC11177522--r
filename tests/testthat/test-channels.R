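test_that("flatlined and high-noise channels are flagged, activation is not", {
  set.seed(21)
  x <- matrix(rnorm(4000 * 64, sd = 0.05), 4000, 64)
  rec <- emg_recording(x, 2000, task_label("mvc"))

  x1 <- x; x1[, 13] <- 0
  bad <- detect_bad_channels(emg_recording(x1, 2000, task_label("mvc")))
  expect_identical(which(bad), 13L)

  x2 <- x; x2[, 40] <- rnorm(4000, sd = 0.5)   # 10x noise SD
  bad <- detect_bad_channels(emg_recording(x2, 2000, task_label("mvc")))
  expect_identical(which(bad), 40L)

  # a genuine focal activation blob must not be flagged
  g <- matrix_to_channels(profile_gains(spatial_profile(
    data.frame(ci = 4.5, cj = 6.5, si = 1.1, sj = 1.1, gain = 0.9),
    floor_gain = 0.1)))
  x3 <- sweep(x, 2, g, `*`)
  expect_false(any(detect_bad_channels(emg_recording(x3, 2000, task_label("mvc")))))
})

test_that("false-flag rate on i.i.d. channels is below 1%", {
  set.seed(22)
  flags <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    x <- matrix(rnorm(1500 * 64, sd = 0.05), 1500, 64)
    flags <- flags + sum(detect_bad_channels(emg_recording(x, 2000, task_label("mvc"))))
  }
  expect_lt(flags / (n_rep * 64), 0.01)
})

test_that("a recording with too many dead channels is rejected", {
  x <- matrix(rnorm(1000 * 64, sd = 0.05), 1000, 64)
  x[, 1:25] <- 0
  expect_error(detect_bad_channels(emg_recording(x, 2000, task_label("mvc"))),
               "quality")
})

test_that("interpolation replaces bad channels by neighbour means", {
  # constant signals: channel (3,3) surrounded by 1, 2, 3, 4 -> 2.5
  vals <- rep(1, 64)
  set_ch <- function(v, i, j, val) { v[grid_to_channel(i, j) + 1] <- val; v }
  vals <- set_ch(vals, 2, 3, 1); vals <- set_ch(vals, 4, 3, 2)
  vals <- set_ch(vals, 3, 2, 3); vals <- set_ch(vals, 3, 4, 4)
  x <- matrix(rep(vals, each = 100), 100, 64)
  rec <- emg_recording(x, 2000, task_label("mvc"))
  bad <- rep(FALSE, 64); bad[grid_to_channel(3, 3) + 1] <- TRUE
  out <- interpolate_bad_channels(rec, bad)
  expect_equal(unique(out$signals[, grid_to_channel(3, 3) + 1]), 2.5)
  expect_false(out$effective_mask[grid_to_channel(3, 3) + 1])

  # corner channel: mean of the two valid edge neighbours
  bad2 <- rep(FALSE, 64); bad2[grid_to_channel(1, 1) + 1] <- TRUE
  nb_mean <- mean(x[1, grid_to_channel(c(1, 2), c(2, 1)) + 1])
  out2 <- interpolate_bad_channels(rec, bad2)
  expect_equal(unique(out2$signals[, grid_to_channel(1, 1) + 1]), nb_mean)
})

test_that("interpolation is identity without bad channels and idempotent", {
  set.seed(23)
  rec <- emg_recording(matrix(rnorm(500 * 64), 500, 64), 2000, task_label("mvc"))
  expect_identical(interpolate_bad_channels(rec, rep(FALSE, 64)), rec)

  bad <- rep(FALSE, 64); bad[c(5, 20)] <- TRUE
  once <- interpolate_bad_channels(rec, bad)
  twice <- interpolate_bad_channels(once, bad)
  expect_equal(once$signals, twice$signals)
  # untouched channels bit-equal
  expect_identical(once$signals[, -c(5, 20)], rec$signals[, -c(5, 20)])
})

test_that("bad channels with no recoverable neighbours raise an error", {
  rec <- const_recording(n = 100)
  expect_error(interpolate_bad_channels(rec, rep(TRUE, 64)), "unrecoverable")
})

test_that("nested bad regions are filled iteratively from the outside in", {
  rec <- const_recording(value = 2, n = 100)
  bad <- rep(FALSE, 64)
  for (i in 3:5) for (j in 3:5) bad[grid_to_channel(i, j) + 1] <- TRUE
  out <- interpolate_bad_channels(rec, bad)
  expect_equal(unique(as.vector(out$signals)), 2)  # constants propagate
  expect_equal(sum(out$effective_mask), 64 - 9)
})
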