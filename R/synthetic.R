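#' Spatial activation profile
#'
#' Gain field over the 8 x 8 grid: a constant background (`floor_gain`,
#' emulating the broad monopolar pick-up common to all channels) plus one or
#' more Gaussian blobs (localised activation sources). Evaluated gains are
#' strictly positive and, for the default subject models, normalised so the
#' peak channel has gain 1.
#'
#' @param blobs data.frame with columns `ci, cj` (centre, grid units),
#'   `si, sj` (SDs, grid units) and `gain` (peak height).
#' @param floor_gain Background gain.
#' @return A `spatial_profile` object.
#' @export
spatial_profile <- function(blobs, floor_gain = 0) {
  blobs <- as.data.frame(blobs)
  stopifnot(all(c("ci", "cj", "si", "sj", "gain") %in% names(blobs)),
            all(blobs$gain > 0), all(blobs$si > 0), all(blobs$sj > 0),
            floor_gain >= 0)
  structure(list(blobs = blobs, floor_gain = floor_gain),
            class = "spatial_profile")
}

#' Evaluate a spatial profile on the grid
#' @param profile A [spatial_profile()].
#' @param grid A [grid_spec()].
#' @return 8 x 8 gain matrix (strictly positive).
#' @export
profile_gains <- function(profile, grid = grid_spec()) {
  i <- matrix(seq_len(grid$n_rows), grid$n_rows, grid$n_cols)
  j <- matrix(seq_len(grid$n_cols), grid$n_rows, grid$n_cols, byrow = TRUE)
  g <- matrix(profile$floor_gain, grid$n_rows, grid$n_cols)
  for (b in seq_len(nrow(profile$blobs))) {
    bb <- profile$blobs[b, ]
    g <- g + bb$gain * exp(-((i - bb$ci)^2 / (2 * bb$si^2) +
                             (j - bb$cj)^2 / (2 * bb$sj^2)))
  }
  if (any(g <= 0)) stop("profile gain field must be strictly positive")
  g
}

# --- default subject-model parameters -------------------------------------
#
# Calibrated once so that the *pipeline outputs* on the default cohort land
# on the group-level values the method is validated against (mean map
# intensities per task, active/passive CoG coordinates, within- and
# between-task cluster overlap); the raw centres/floors are free knobs with
# no direct empirical counterpart. See the methods vignette for the
# calibration procedure.
.model_defaults <- function(group) {
  if (group == "healthy") {
    list(
      mvc_amplitude_mv = 0.5,
      mvc_force_n = 250,
      active_blobs = data.frame(
        ci = c(5.25, 5.25), cj = c(3.25, 5.9),
        si = 1.2, sj = 1.2, gain = 0.62 * c(1.0, 0.92)),
      active_floor = 0.35,
      passive_blobs = NULL,                 # no reflex source
      passive_floor = 1,
      force_emg_exponent = 1.25,
      baseline_tone = 0.0105,               # fraction of mvc_amplitude
      reflex_rel = c("60" = 0, "120" = 0, "180" = 0),
      line_noise_mv = 0.03,
      sensor_noise_mv = 0.002,
      trial_jitter_sd = 0.12)
  } else {
    list(
      mvc_amplitude_mv = 0.5,
      mvc_force_n = 180,
      active_blobs = data.frame(
        ci = 4.52, cj = 4.2, si = 1.3, sj = 1.3, gain = 0.69),
      active_floor = 0.29,
      # broad central component (diffuse reflex background over the muscle
      # belly, keeps the CoG near mid-grid) + steep distal reflex focus
      # (segments into a stable cluster)
      passive_blobs = data.frame(
        ci = c(4.5, 4.6), cj = c(3.75, 6.55),
        si = c(2.3, 1.05), sj = c(2.3, 1.05), gain = c(0.25, 0.80)),
      passive_floor = 0.45,
      force_emg_exponent = 0.55,
      baseline_tone = 0.045,
      reflex_rel = c("60" = 0.078, "120" = 0.160, "180" = 0.220),
      line_noise_mv = 0.03,
      sensor_noise_mv = 0.002,
      trial_jitter_sd = 0.12)
  }
}

# between-subject jitter settings
.jitter_centre_sd <- 0.35    # grid units, blob centres
.jitter_gain_cv <- 0.3       # lognormal CV on amplitudes/gains

.rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw a synthetic subject model
#'
#' Samples one subject's generative parameters around the group defaults:
#' blob centres are jittered with SD 0.35 grid units and amplitudes with
#' lognormal CV 0.3. Spastic subjects have a single voluntary-activation
#' blob plus a distally-centred reflex profile with velocity-dependent gain
#' (non-decreasing over 60/120/180 deg/s); healthy subjects have the
#' two-blob (innervation-zone split) voluntary pattern and zero reflex gain.
#' Uses the current RNG stream; seed it for reproducibility.
#'
#' @param group `"healthy"` or `"spastic"`.
#' @param subject_id Identifier stored with the model.
#' @param n_bad_channels Number of bad channels (0--2 drawn uniformly if
#'   `NULL`).
#' @return A `subject_model` object.
#' @export
make_subject <- function(group = c("healthy", "spastic"),
                         subject_id = NA_character_, n_bad_channels = NULL) {
  group <- match.arg(group)
  d <- .model_defaults(group)
  jit_blobs <- function(blobs) {
    if (is.null(blobs)) return(NULL)
    blobs$ci <- blobs$ci + stats::rnorm(nrow(blobs), 0, .jitter_centre_sd)
    blobs$cj <- blobs$cj + stats::rnorm(nrow(blobs), 0, .jitter_centre_sd)
    blobs
  }
  # floor jitter gives subjects realistic spread in mean map intensity
  # (blob gains largely cancel through MVC normalisation)
  active_profile <- spatial_profile(jit_blobs(d$active_blobs),
                                    floor_gain = d$active_floor *
                                      .rlnorm_cv(1, 0.25))
  passive_profile <- if (is.null(d$passive_blobs)) {
    spatial_profile(data.frame(ci = 4.5, cj = 4.5, si = 2, sj = 2, gain = 1e-9),
                    floor_gain = 1)
  } else {
    spatial_profile(jit_blobs(d$passive_blobs), floor_gain = d$passive_floor)
  }
  if (is.null(n_bad_channels)) n_bad_channels <- sample(0:2, 1)
  bad <- if (n_bad_channels > 0) sort(sample(64L, n_bad_channels)) else integer(0)
  structure(list(
    subject_id = subject_id,
    group = group,
    mvc_amplitude_mv = d$mvc_amplitude_mv * .rlnorm_cv(1, .jitter_gain_cv),
    mvc_force_n = d$mvc_force_n * .rlnorm_cv(1, 0.15),
    active_profile = active_profile,
    passive_profile = passive_profile,
    force_emg_exponent = d$force_emg_exponent,
    baseline_tone = d$baseline_tone * .rlnorm_cv(1, .jitter_gain_cv),
    reflex_rel = d$reflex_rel * .rlnorm_cv(1, 0.22),
    line_noise_mv = d$line_noise_mv * stats::runif(1, 0.5, 1.5),
    sensor_noise_mv = d$sensor_noise_mv,
    trial_jitter_sd = d$trial_jitter_sd,
    bad_channels = bad,
    bad_channel_flat = stats::runif(length(bad)) < 0.5),
    class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model> %s (%s): MVC %.2f mV, tone %.3f, %d bad channel(s)\n",
              x$subject_id, x$group, x$mvc_amplitude_mv, x$baseline_tone,
              length(x$bad_channels)))
  invisible(x)
}

#' Synthesize a multichannel EMG block
#'
#' Per channel: `gain * envelope(t) * carrier(t) + line + sensor noise`,
#' where the carrier is zero-mean band-limited (20--450 Hz) Gaussian noise
#' scaled to unit variance, so the expected windowed RMS of the clean term
#' equals `gain * envelope` level. The carrier band sits inside the
#' pipeline's 20--500 Hz passband so preprocessing does not bias amplitude
#' calibration. Line interference is a 50 Hz sinusoid with random phase,
#' common across channels up to a small per-channel amplitude jitter.
#'
#' @param gains Length-64 per-channel gain (mV).
#' @param envelope Amplitude envelope, one value per sample (dimensionless).
#' @param fs_hz Sampling rate.
#' @param line_amp_mv 50 Hz interference amplitude (0 disables).
#' @param noise_sd_mv White sensor-noise SD (0 disables).
#' @param band_hz Carrier band (Hz).
#' @return Samples x 64 signal matrix (mV).
#' @export
synthesize_emg <- function(gains, envelope, fs_hz = 2000, line_amp_mv = 0,
                           noise_sd_mv = 0, band_hz = c(20, 450)) {
  S <- length(envelope)
  stopifnot(S >= 2, length(gains) == 64)
  x <- .synth_carrier(S, fs_hz, band_hz) * envelope   # recycles down columns
  x <- sweep(x, 2L, gains, `*`)
  .add_line_and_noise(x, fs_hz, line_amp_mv, noise_sd_mv)
}

# unit-variance band-limited Gaussian carrier, independent per channel
.synth_carrier <- function(S, fs_hz, band_hz = c(20, 450), n_ch = 64) {
  white <- matrix(stats::rnorm(S * n_ch), S, n_ch)
  f <- (seq_len(S) - 1) * fs_hz / S
  keep <- (f >= band_hz[1] & f <= band_hz[2]) |
          (f >= fs_hz - band_hz[2] & f <= fs_hz - band_hz[1])
  W <- stats::mvfft(white)
  W[!keep, ] <- 0
  carrier <- Re(stats::mvfft(W, inverse = TRUE)) / S
  sweep(carrier, 2L, sqrt(colMeans(carrier^2)), `/`)
}

.add_line_and_noise <- function(x, fs_hz, line_amp_mv, noise_sd_mv) {
  S <- nrow(x)
  if (line_amp_mv > 0) {
    ph <- stats::runif(1, 0, 2 * pi)
    line <- line_amp_mv * sin(2 * pi * 50 * (seq_len(S) - 1) / fs_hz + ph)
    x <- x + outer(line, stats::runif(ncol(x), 0.8, 1.2))
  }
  if (noise_sd_mv > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, noise_sd_mv), S, ncol(x))
  x
}

# raised-cosine on/off ramp helper: value 0 -> 1 over `n` samples
.cos_ramp <- function(n) (1 - cos(pi * seq_len(n) / n)) / 2

# task component (gain x envelope) on top of the resting-tone amplitude:
# task activity recruits motor units coherently with the ongoing background
# drive, so the two envelopes add in amplitude and the resting map subtracts
# out of task maps exactly (one carrier synthesis per trial)
.synth_mixed <- function(task_g, env, tone_g, fs_hz, line_amp_mv, noise_sd_mv) {
  S <- length(env)
  amp <- outer(env, task_g) + outer(rep(1, S), tone_g)
  x <- .synth_carrier(S, fs_hz) * amp
  .add_line_and_noise(x, fs_hz, line_amp_mv, noise_sd_mv)
}

#' Simulate one trial of the protocol
#'
#' Passive trials: the joint-angle trace ramps 90 -> 180 deg at the task
#' velocity (the stretch), holds, and starts the return (truncated; only the
#' first extension is analysed). The EMG envelope is the subject's resting
#' tone plus, in spastic subjects at 60/120/180 deg/s, a reflex plateau
#' during the extension shaped by the passive (reflex) profile. Active
#' trials: a 7 s isometric hold at `level` x MVC force (2% multiplicative
#' noise on the force trace) preceded by a short ramp; the EMG envelope is
#' `level^force_emg_exponent` shaped by the voluntary profile. MVC trials:
#' 5 s at envelope 1. Bad channels are flatlined or overwritten with
#' high-amplitude noise per the subject model. Uses the current RNG stream.
#'
#' @param subject A `subject_model` from [make_subject()].
#' @param task A [task_label()].
#' @param fs_hz Sampling rate.
#' @return An [emg_recording()].
#' @export
simulate_trial <- function(subject, task, fs_hz = 2000) {
  stopifnot(inherits(subject, "subject_model"), inherits(task, "task_label"))
  if (!task$kind %in% c("passive", "active", "mvc"))
    stop(sprintf("protocol error: unknown task kind '%s'", task$kind))
  amp <- subject$mvc_amplitude_mv
  # trial-to-trial wander of the activation centres (grid units): real
  # activation maps are not perfectly repeatable across trials
  jit <- function(p) {
    sdj <- subject$trial_jitter_sd %||% 0
    if (sdj <= 0) return(p)
    p$blobs$ci <- p$blobs$ci + stats::rnorm(nrow(p$blobs), 0, sdj)
    p$blobs$cj <- p$blobs$cj + stats::rnorm(nrow(p$blobs), 0, sdj)
    p
  }
  active_g <- matrix_to_channels(profile_gains(jit(subject$active_profile))) * amp
  passive_g <- matrix_to_channels(profile_gains(jit(subject$passive_profile))) * amp
  tone_g <- rep(subject$baseline_tone * amp, 64)
  ramp_n <- round(0.05 * fs_hz)

  if (task$kind == "passive") {
    v <- task$level
    lead_n <- round(0.5 * fs_hz)
    ext_n <- round(90 / v * fs_hz)
    hold_n <- round(0.5 * fs_hz)
    ret_n <- round(min(90 / v, 1.5) * fs_hz)
    angle <- c(rep(90, lead_n),
               90 + seq_len(ext_n) * v / fs_hz,
               rep(180, hold_n),
               180 - seq_len(ret_n) * v / fs_hz)
    S <- length(angle)
    aux <- angle + stats::rnorm(S, 0, 0.1)
    rlv <- if (v >= 60) unname(subject$reflex_rel[as.character(v)]) else 0
    env <- numeric(S)
    if (rlv > 0) {
      plateau <- rep(1, ext_n)
      nr <- min(ramp_n, ext_n %/% 2)
      plateau[seq_len(nr)] <- .cos_ramp(nr)
      plateau[ext_n - seq_len(nr) + 1] <- .cos_ramp(nr)
      env[lead_n + seq_len(ext_n)] <- rlv * plateau
    }
    x <- .synth_mixed(passive_g, env, tone_g, fs_hz, subject$line_noise_mv,
                      subject$sensor_noise_mv)
  } else if (task$kind == "active") {
    lead_n <- round(0.5 * fs_hz)
    rampup_n <- round(0.5 * fs_hz)
    hold_n <- round(7 * fs_hz)
    target <- task$level * subject$mvc_force_n
    f_clean <- c(rep(0, lead_n), target * .cos_ramp(rampup_n), rep(target, hold_n))
    S <- length(f_clean)
    aux <- f_clean * (1 + stats::rnorm(S, 0, 0.02))
    env <- (f_clean / subject$mvc_force_n)^subject$force_emg_exponent
    x <- .synth_mixed(active_g, env, tone_g, fs_hz, subject$line_noise_mv,
                      subject$sensor_noise_mv)
  } else {                                       # mvc
    rampup_n <- round(0.3 * fs_hz)
    hold_n <- round(4.7 * fs_hz)
    env <- c(.cos_ramp(rampup_n), rep(1, hold_n))
    S <- length(env)
    aux <- subject$mvc_force_n * env * (1 + stats::rnorm(S, 0, 0.02))
    x <- .synth_mixed(active_g, env, tone_g, fs_hz, subject$line_noise_mv,
                      subject$sensor_noise_mv)
  }

  if (length(subject$bad_channels) > 0) {
    med_rms <- stats::median(sqrt(colMeans(x^2)))
    for (k in seq_along(subject$bad_channels)) {
      ch <- subject$bad_channels[k]
      x[, ch] <- if (subject$bad_channel_flat[k]) 0
                 else stats::rnorm(nrow(x), 0, 10 * med_rms)
    }
  }
  emg_recording(x, fs_hz, task, aux = aux, subject_id = subject$subject_id)
}

#' Simulate all 24 recordings of one subject
#'
#' Full protocol: 3 MVC trials, 3 trials at each of 4 stretch velocities,
#' 3 trials at each of 3 contraction levels.
#'
#' @param subject A `subject_model`.
#' @param fs_hz Sampling rate.
#' @return Named list of 24 [emg_recording()]s.
#' @export
simulate_subject_recordings <- function(subject, fs_hz = 2000) {
  recs <- list()
  for (tr in 1:3)
    recs[[sprintf("mvc_%d", tr)]] <-
      simulate_trial(subject, task_label("mvc", trial = tr), fs_hz)
  for (v in c(10, 60, 120, 180)) for (tr in 1:3)
    recs[[sprintf("passive_%03d_%d", v, tr)]] <-
      simulate_trial(subject, task_label("passive", v, tr), fs_hz)
  for (lv in c(0.2, 0.5, 0.8)) for (tr in 1:3)
    recs[[sprintf("active_%02d_%d", round(lv * 100), tr)]] <-
      simulate_trial(subject, task_label("active", lv, tr), fs_hz)
  recs
}

#' Simulate a cohort
#'
#' Draws `n_spastic` + `n_healthy` subject models and their full recording
#' protocols. With `path`, the dataset is written to disk in the package's
#' dataset layout (recordings are generated and written one subject at a
#' time to bound memory); otherwise all recordings are returned in memory
#' (use small cohorts). The manifest records the seed and per-subject model
#' parameters for auditability.
#'
#' @param n_spastic,n_healthy Group sizes (study defaults 14 and 10).
#' @param seed Integer seed controlling every random draw.
#' @param path Optional dataset directory to write.
#' @param fs_hz Sampling rate.
#' @return Invisibly, a list with `subjects` (models) and, when `path` is
#'   `NULL`, `recordings` (per-subject lists).
#' @export
simulate_cohort <- function(n_spastic = 14, n_healthy = 10, seed = 1,
                            path = NULL, fs_hz = 2000) {
  stopifnot(n_spastic >= 1, n_healthy >= 1)
  set.seed(seed)
  groups <- c(rep("spastic", n_spastic), rep("healthy", n_healthy))
  ids <- c(sprintf("S%02d", seq_len(n_spastic)),
           sprintf("H%02d", seq_len(n_healthy)))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  subjects <- recordings <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(path)) .init_dataset_dir(path, seed)
  for (k in seq_along(ids)) {
    set.seed(subject_seeds[k])
    subj <- make_subject(groups[k], subject_id = ids[k])
    subjects[[k]] <- subj
    recs <- simulate_subject_recordings(subj, fs_hz)
    if (is.null(path)) {
      recordings[[k]] <- recs
    } else {
      .write_subject_recordings(path, ids[k], recs)
    }
  }
  if (!is.null(path)) .finalize_manifest(path, subjects, seed, subject_seeds)
  invisible(list(subjects = subjects,
                 groups = stats::setNames(groups, ids),
                 recordings = if (is.null(path)) recordings else NULL,
                 seed = seed))
}
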