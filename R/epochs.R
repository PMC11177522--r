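#' Extract the passive-stretch epoch from a passive trial
#'
#' The stretch of the biceps is the elbow *extension* phase. The epoch is the
#' first contiguous span where the smoothed angular velocity of the joint
#' trace exceeds `vel_on_frac` times the nominal task velocity, i.e. from
#' movement onset at ~90 deg flexion until the extension stops.
#'
#' @param rec A passive [emg_recording()] with a joint-angle `aux` trace
#'   (degrees; increasing = extension).
#' @param vel_on_frac Onset threshold as a fraction of nominal velocity.
#' @param smooth_s Moving-average length (s) for the velocity estimate.
#' @return An [emg_epoch()] covering the first extension.
#' @export
extract_passive_stretch_epoch <- function(rec, vel_on_frac = 0.5,
                                          smooth_s = 0.05) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$task$kind != "passive")
    stop("segmentation error: not a passive trial")
  if (is.null(rec$aux))
    stop("segmentation error: passive trial has no joint-angle trace")
  fs <- rec$fs_hz
  # central difference over a 50 ms half-window, then moving-average
  # smoothing: sample-wise differentiation would amplify angle-sensor noise
  # far above the nominal velocities
  ang <- rec$aux
  S <- length(ang)
  d <- max(1L, round(0.05 * fs))
  vel <- numeric(S)
  idx <- (d + 1L):(S - d)
  vel[idx] <- (ang[idx + d] - ang[idx - d]) * fs / (2 * d)
  k <- max(1L, round(smooth_s * fs))
  vel <- as.numeric(stats::filter(vel, rep(1 / k, k), sides = 2))
  vel[is.na(vel)] <- 0
  thr <- vel_on_frac * rec$task$level
  above <- vel > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- max(2L, round(0.05 * fs))       # ignore sub-50 ms flickers
  cand <- which(r$values & r$lengths >= min_len)
  if (length(cand) == 0)
    stop("segmentation error: no extension phase found in angle trace")
  emg_epoch(rec, starts[cand[1]], ends[cand[1]] + 1L)
}

#' Extract a stable active-contraction epoch
#'
#' Selects the `window_s` (default 3 s) window of the force trace with the
#' lowest coefficient of variation, scanning start positions on a `step_s`
#' grid; ties go to the earliest window. This operationalises "stable
#' contraction" for the 7 s submaximal trials.
#'
#' @param rec An active [emg_recording()] with a force `aux` trace.
#' @param window_s Epoch length in seconds.
#' @param step_s Scan step in seconds.
#' @return An [emg_epoch()].
#' @export
extract_active_epoch <- function(rec, window_s = 3, step_s = 0.1) {
  stopifnot(inherits(rec, "emg_recording"))
  if (is.null(rec$aux))
    stop("segmentation error: active trial has no force trace")
  fs <- rec$fs_hz
  S <- nrow(rec$signals)
  n <- round(window_s * fs)
  if (S < n)
    stop(sprintf("length error: recording (%.2f s) shorter than the %g s window",
                 S / fs, window_s))
  f <- rec$aux
  cs <- c(0, cumsum(f))
  cs2 <- c(0, cumsum(f^2))
  starts <- seq(1L, S - n + 1L, by = max(1L, round(step_s * fs)))
  m <- (cs[starts + n] - cs[starts]) / n
  v <- pmax(0, (cs2[starts + n] - cs2[starts]) / n - m^2)
  cv <- ifelse(abs(m) < .Machine$double.eps^0.5, Inf, sqrt(v) / abs(m))
  best <- which.min(cv)                      # which.min takes the earliest tie
  emg_epoch(rec, starts[best], starts[best] + n)
}

#' Select the analysis epoch among repeated trials
#'
#' Of the (up to three) candidate epochs of one condition, the one recorded
#' with the most effective (non-interpolated) channels is analysed; ties go
#' to the lowest trial index.
#'
#' @param epochs List of [emg_epoch()] objects of the same condition.
#' @return The selected epoch.
#' @export
select_trial_epoch <- function(epochs) {
  if (length(epochs) == 0)
    stop("missing data: no candidate epochs for this condition")
  counts <- vapply(epochs, function(e) e$n_effective, numeric(1))
  epochs[[which.max(counts)]]
}
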