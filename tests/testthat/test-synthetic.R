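test_that("subject models follow the group construction rules", {
  set.seed(71)
  h <- make_subject("healthy", "H")
  s <- make_subject("spastic", "S")
  expect_equal(nrow(h$active_profile$blobs), 2)   # innervation-zone split
  expect_equal(unname(h$reflex_rel), c(0, 0, 0))  # no stretch reflex
  expect_equal(nrow(s$active_profile$blobs), 1)
  # the reflex focus sits distal of the voluntary centre
  expect_gt(max(s$passive_profile$blobs$cj), s$active_profile$blobs$cj[1])
  # reflex gain is non-decreasing in stretch velocity
  expect_true(all(diff(s$reflex_rel) >= 0))
  expect_gt(s$mvc_amplitude_mv, 0)
  # identical RNG state reproduces the model exactly
  set.seed(72); a <- make_subject("spastic", "S")
  set.seed(72); b <- make_subject("spastic", "S")
  expect_identical(a, b)
})

test_that("synthesized EMG is amplitude-calibrated", {
  set.seed(73)
  # zero envelope, no line: pure sensor noise of SD 0.002 mV
  x <- synthesize_emg(rep(1, 64), rep(0, 4000), noise_sd_mv = 0.002)
  expect_equal(mean(sqrt(colMeans(x^2))), 0.002, tolerance = 0.2)

  # doubling the gain doubles the RMS (mean over 10 draws within 5%)
  set.seed(74)
  ratios <- replicate(10, {
    env <- rep(1, 2000)
    r1 <- sqrt(mean(synthesize_emg(rep(0.2, 64), env)^2))
    r2 <- sqrt(mean(synthesize_emg(rep(0.4, 64), env)^2))
    r2 / r1
  })
  expect_equal(mean(ratios), 2, tolerance = 0.05)

  # unit gain, unit envelope: RMS ~ 1
  set.seed(75)
  x2 <- synthesize_emg(rep(1, 64), rep(1, 4000))
  expect_equal(mean(sqrt(colMeans(x2^2))), 1, tolerance = 0.05)
})

test_that("line interference shows as a 50 Hz spectral peak >= 20 dB", {
  set.seed(76)
  fs <- 2000; S <- 4000
  x <- synthesize_emg(rep(0.1, 64), rep(1, S), fs, line_amp_mv = 0.05)
  spec <- Mod(fft(x[, 1]))^2
  f <- (seq_len(S) - 1) * fs / S
  i50 <- which.min(abs(f - 50))
  neigh <- c(i50 - (8:4), i50 + (4:8))
  expect_gt(10 * log10(spec[i50] / mean(spec[neigh])), 20)
})

test_that("passive trials follow the stretch kinematics and reflex rules", {
  set.seed(77)
  s <- make_subject("spastic", "S", n_bad_channels = 0)
  h <- make_subject("healthy", "H", n_bad_channels = 0)

  # 10 deg/s: extension phase lasts 90/10 = 9 s
  rec10 <- simulate_trial(s, task_label("passive", 10))
  ep <- extract_passive_stretch_epoch(rec10)
  expect_equal((ep$end - ep$start) / rec10$fs_hz, 9, tolerance = 0.1)

  # healthy stretch response stays near resting level
  rech <- simulate_trial(h, task_label("passive", 180))
  eph <- extract_passive_stretch_epoch(rech)
  stretch_amp <- mean(abs(epoch_signals(eph)))
  rest_amp <- mean(abs(rech$signals[1:900, ]))
  expect_lt(stretch_amp, 1.5 * rest_amp)

  # spastic stretch envelope grows with velocity, every trial
  for (r in 1:3) {
    e60 <- simulate_trial(s, task_label("passive", 60))
    e180 <- simulate_trial(s, task_label("passive", 180))
    a60 <- mean(abs(epoch_signals(extract_passive_stretch_epoch(e60))))
    a180 <- mean(abs(epoch_signals(extract_passive_stretch_epoch(e180))))
    expect_gt(a180, a60)
  }

  expect_error(simulate_trial(s, structure(list(kind = "jump", trial = 1),
                                           class = "task_label")))
})

test_that("simulated cohorts have the full protocol and are reproducible", {
  set.seed(78)
  s <- make_subject("spastic", "S", n_bad_channels = 0)
  recs <- simulate_subject_recordings(s)
  kinds <- vapply(recs, function(r) r$task$kind, character(1))
  expect_length(recs, 24)
  expect_equal(sum(kinds == "mvc"), 3)
  expect_equal(sum(kinds == "passive"), 12)
  expect_equal(sum(kinds == "active"), 9)

  co1 <- simulate_cohort(n_spastic = 1, n_healthy = 1, seed = 5)
  co2 <- simulate_cohort(n_spastic = 1, n_healthy = 1, seed = 5)
  expect_identical(co1$recordings, co2$recordings)
  expect_identical(names(co1$recordings), c("S01", "H01"))
  expect_equal(unname(co1$groups), c("spastic", "healthy"))
})
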