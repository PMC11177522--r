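#' Task label for a recording
#'
#' The protocol comprises passive isokinetic stretches at four angular
#' velocities (10, 60, 120, 180 deg/s), isometric contractions at three
#' submaximal levels (20, 50, 80 %MVC) and three maximum voluntary
#' contraction (MVC) trials.
#'
#' @param kind One of `"passive"`, `"active"`, `"mvc"`.
#' @param level Stretch velocity in deg/s (passive) or contraction level as a
#'   fraction of MVC (active); `NA` for MVC trials.
#' @param trial Trial index, 1..3.
#' @return A `task_label` object.
#' @export
task_label <- function(kind, level = NA_real_, trial = 1L) {
  kind <- match.arg(kind, c("passive", "active", "mvc"))
  trial <- as.integer(trial)
  if (!trial %in% 1:3) stop("trial must be in 1..3")
  if (kind == "passive" && !level %in% c(10, 60, 120, 180))
    stop("passive stretch velocity must be one of 10, 60, 120, 180 deg/s")
  if (kind == "active" && !isTRUE(all.equal(min(abs(level - c(0.2, 0.5, 0.8))), 0)))
    stop("active contraction level must be one of 0.2, 0.5, 0.8 (fraction of MVC)")
  if (kind == "mvc") level <- NA_real_
  structure(list(kind = kind, level = level, trial = trial),
            class = "task_label")
}

#' Compact condition identifier such as "passive_060" or "active_20"
#' (trial index not included).
#' @param task A [task_label()].
#' @export
task_id <- function(task) {
  switch(task$kind,
         passive = sprintf("passive_%03d", as.integer(task$level)),
         active  = sprintf("active_%02d", as.integer(round(task$level * 100))),
         mvc     = "mvc")
}

#' @export
print.task_label <- function(x, ...) {
  cat(sprintf("<task> %s trial %d\n", task_id(x), x$trial))
  invisible(x)
}

#' Multichannel EMG recording
#'
#' A single trial of monopolar HD-sEMG: an S x 64 signal matrix (mV; columns
#' are channels 0..63 in grid row-major order), the sampling rate, the task
#' label, an optional auxiliary trace (joint angle in degrees for passive
#' trials, force in N for active/MVC trials), and a per-channel effective
#' mask (FALSE marks channels excluded or synthesised by interpolation).
#'
#' @param signals Numeric matrix, samples x 64, in mV.
#' @param fs_hz Sampling rate in Hz (2000 for this protocol).
#' @param task A [task_label()].
#' @param aux Optional auxiliary trace, same number of samples as `signals`.
#' @param effective_mask Logical length-64; TRUE = usable channel.
#' @param subject_id Subject identifier string.
#' @param grid A [grid_spec()].
#' @return An `emg_recording` object.
#' @export
emg_recording <- function(signals, fs_hz, task, aux = NULL,
                          effective_mask = rep(TRUE, 64L),
                          subject_id = NA_character_, grid = grid_spec()) {
  if (!is.matrix(signals)) signals <- as.matrix(signals)
  n_ch <- grid$n_rows * grid$n_cols
  if (ncol(signals) != n_ch)
    stop(sprintf("geometry error: expected %d channels, got %d", n_ch, ncol(signals)))
  stopifnot(nrow(signals) >= 1, fs_hz > 0, inherits(task, "task_label"))
  if (!is.null(aux) && length(aux) != nrow(signals))
    stop("aux trace length must equal the number of samples")
  stopifnot(length(effective_mask) == n_ch, is.logical(effective_mask))
  structure(
    list(signals = signals, fs_hz = fs_hz, task = task, aux = aux,
         effective_mask = effective_mask, subject_id = subject_id,
         grid = grid, filtered = FALSE),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s %s trial %d: %d samples @ %g Hz, %d/%d effective%s\n",
              x$subject_id, task_id(x$task), x$task$trial, nrow(x$signals),
              x$fs_hz, sum(x$effective_mask), length(x$effective_mask),
              if (isTRUE(x$filtered)) ", filtered" else ""))
  invisible(x)
}

#' Epoch of a recording
#'
#' A half-open sample range `[start, end)` (1-based start; samples
#' `start .. end - 1`) of a parent recording, carrying its task label and the
#' number of effective channels (used for trial selection).
#'
#' @param recording Parent [emg_recording()].
#' @param start,end Sample indices, 1-based half-open; `1 <= start < end <=
#'   nrow(signals) + 1`.
#' @return An `emg_epoch` object.
#' @export
emg_epoch <- function(recording, start, end) {
  stopifnot(inherits(recording, "emg_recording"))
  S <- nrow(recording$signals)
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 1 && start < end && end <= S + 1L))
    stop("epoch bounds out of range")
  structure(list(recording = recording, start = start, end = end,
                 task = recording$task,
                 n_effective = sum(recording$effective_mask)),
            class = "emg_epoch")
}

#' Signal matrix of an epoch
#' @param ep An [emg_epoch()].
#' @return Samples x 64 matrix.
#' @export
epoch_signals <- function(ep) {
  stopifnot(inherits(ep, "emg_epoch"))
  ep$recording$signals[ep$start:(ep$end - 1L), , drop = FALSE]
}

#' @export
print.emg_epoch <- function(x, ...) {
  cat(sprintf("<emg_epoch> %s [%d, %d) = %.3f s, %d effective channels\n",
              task_id(x$task), x$start, x$end,
              (x$end - x$start) / x$recording$fs_hz, x$n_effective))
  invisible(x)
}
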