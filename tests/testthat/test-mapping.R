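test_that("windowed RMS matches closed forms", {
  fs <- 2000
  # constant c over 2 full windows -> |c|
  ep <- emg_epoch(const_recording(value = -0.3, n = 800), 1, 801)
  expect_equal(unique(as.vector(windowed_rms(ep)$values)), 0.3)

  # unit sinusoid with integer cycles per window -> 1/sqrt(2)
  t <- seq_len(800) / fs
  ep2 <- emg_epoch(trace_recording(sin(2 * pi * 100 * t), fs), 1, 801)
  expect_equal(unique(round(as.vector(windowed_rms(ep2)$values), 6)),
               round(1 / sqrt(2), 6), tolerance = 1e-6)

  # 500 ms at 2 kHz: two full 200 ms windows, 200 samples discarded
  ep3 <- emg_epoch(const_recording(value = 1, n = 1000), 1, 1001)
  expect_equal(windowed_rms(ep3)$n_windows, 2)

  # shorter than one window
  ep4 <- emg_epoch(const_recording(n = 300), 1, 301)
  expect_error(windowed_rms(ep4), "length")
})

test_that("windowed RMS of concatenated identical windows equals one window", {
  set.seed(41)
  w <- rnorm(400)
  one <- windowed_rms(emg_epoch(trace_recording(w), 1, 401))
  three <- windowed_rms(emg_epoch(trace_recording(rep(w, 3)), 1, 1201))
  expect_equal(one$values, three$values, tolerance = 1e-12)
})

test_that("RMS_max takes the maximum single window over trials and channels", {
  expect_equal(mvc_rms_max(list(const_recording(value = 0.7, n = 1000))), 0.7)

  # one trial carries a 1-window burst 10x the rest on one channel
  x <- matrix(0.1, 2000, 64)
  x[401:800, 30] <- 1
  burst <- emg_recording(x, 2000, task_label("mvc"))
  expect_equal(mvc_rms_max(list(const_recording(value = 0.1, n = 2000), burst)), 1)

  expect_error(mvc_rms_max(list()), "missing")

  # RMS_max >= every averaged windowed RMS of epochs from those trials
  set.seed(42)
  recs <- lapply(1:3, function(i)
    emg_recording(matrix(rnorm(2000 * 64, sd = 0.2), 2000, 64), 2000,
                  task_label("mvc", trial = i)))
  rmax <- mvc_rms_max(recs)
  for (rec in recs)
    expect_true(all(windowed_rms(emg_epoch(rec, 1, 2001))$values <= rmax))
})

test_that("map construction, baseline subtraction and averaging are exact", {
  rg <- list(values = matrix(0.3, 8, 8), n_windows = 2, window_s = 0.2)
  m <- build_map(rg, 1.2, "S", task_label("active", 0.5))
  expect_equal(unique(as.vector(m$values)), 0.25)
  expect_error(build_map(rg, 0), "normalization")
  rg0 <- list(values = matrix(0, 8, 8), n_windows = 2, window_s = 0.2)
  expect_equal(sum(build_map(rg0, 1)$values), 0)

  a <- point_map(c(2, 2, 0.10), base = 0.02)
  b <- point_map(c(2, 2, 0.04), base = 0.04)
  d <- subtract_baseline(a, b)
  expect_equal(d$values[2, 2], 0.06)
  expect_equal(d$values[1, 1], 0)            # 0.02 - 0.04 clamps to 0
  expect_true(d$baseline_subtracted)
  expect_equal(sum(subtract_baseline(a, a)$values), 0)
  expect_true(all(d$values <= a$values))

  b2 <- b; b2$subject_id <- "OTHER"
  expect_error(subtract_baseline(a, b2), "pairing")

  avg <- average_maps(list(point_map(c(1, 1, 1), base = 0.1),
                           point_map(c(1, 1, 1), base = 0.3)), "passive_avg")
  expect_equal(avg$values[8, 8], 0.2)
  expect_error(average_maps(list()), "missing")
})

test_that("mean intensity is the plain mean of the 64 values", {
  expect_equal(mean_intensity(point_map(base = 1)), 1)
  expect_equal(mean_intensity(point_map(c(3, 7, 0.64))), 0.01)
  expect_equal(mean_intensity(point_map()), 0)
  # averaging commutes with mean intensity (linearity)
  set.seed(43)
  maps <- lapply(1:4, function(i)
    activation_map(matrix(runif(64), 8, 8), subject_id = "T", task = "t"))
  expect_equal(mean_intensity(average_maps(maps)),
               mean(sapply(maps, mean_intensity)), tolerance = 1e-12)
})

test_that("display upsampling is a true interpolant", {
  expect_equal(unique(round(as.vector(upsample_for_display(point_map(base = 0.7))), 9)),
               0.7)
  # passes through the knots
  set.seed(44)
  m <- activation_map(matrix(runif(64), 8, 8), "T", "t")
  img <- upsample_for_display(m)
  knots <- round(seq(1, 71, length.out = 8))
  expect_equal(img[knots, knots], m$values, tolerance = 1e-9)
  # reproduces linear ramps
  ramp <- activation_map(matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8),
                         "T", "t")
  img2 <- upsample_for_display(ramp)
  expect_equal(img2[, 36], rep(0.5, 71), tolerance = 1e-9)
  expect_equal(dim(img), c(71, 71))
})

test_that("the nRMS map is invariant to overall signal scale", {
  set.seed(45)
  subj <- single_blob_subject(4.5, 4.5)
  set.seed(46)
  mvc <- simulate_trial(subj, task_label("mvc"))
  set.seed(47)
  act <- simulate_trial(subj, task_label("active", 0.5))
  scale_rec <- function(rec, k) { rec$signals <- rec$signals * k; rec }
  map_for <- function(mvc, act) {
    rmax <- mvc_rms_max(list(apply_filters(mvc)))
    build_map(windowed_rms(extract_active_epoch(apply_filters(act))), rmax, "X")
  }
  m1 <- map_for(mvc, act)
  m2 <- map_for(scale_rec(mvc, 3.7), scale_rec(act, 3.7))
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
})
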