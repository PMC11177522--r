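#' Windowed RMS per channel
#'
#' For each channel, the epoch is cut into non-overlapping windows of
#' `window_s` (200 ms at 2 kHz = 400 samples); the RMS of each window is
#' computed and averaged over the M full windows. A trailing partial window
#' is discarded, which keeps the per-window statistics unbiased (this
#' matters for the short 180 deg/s stretch epochs, where M = 2).
#'
#' @param ep An [emg_epoch()] (or a samples x 64 matrix plus `fs_hz`).
#' @param window_s Window length in seconds.
#' @param fs_hz Sampling rate; taken from the epoch if omitted.
#' @return An `rms_grid`: list with `values` (8 x 8 matrix, mV),
#'   `n_windows` (M) and `window_s`.
#' @export
windowed_rms <- function(ep, window_s = 0.2, fs_hz = NULL) {
  if (inherits(ep, "emg_epoch")) {
    x <- epoch_signals(ep)
    fs_hz <- ep$recording$fs_hz
    grid <- ep$recording$grid
  } else {
    x <- as.matrix(ep)
    if (is.null(fs_hz)) stop("fs_hz required when passing a raw matrix")
    grid <- grid_spec()
  }
  N <- round(window_s * fs_hz)
  M <- nrow(x) %/% N
  if (M < 1)
    stop(sprintf("length error: epoch (%d samples) shorter than one %g s window",
                 nrow(x), window_s))
  per_win <- .window_rms_matrix(x, N, M)       # M x 64
  structure(list(values = channels_to_matrix(colMeans(per_win), grid),
                 n_windows = M, window_s = window_s),
            class = "rms_grid")
}

# per-window RMS: returns an M x n_channels matrix
.window_rms_matrix <- function(x, N, M) {
  x2 <- x[seq_len(M * N), , drop = FALSE]^2
  dim(x2) <- c(N, M * ncol(x))
  w <- sqrt(colMeans(x2))
  dim(w) <- c(M, ncol(x))
  w
}

#' Subject normalisation constant from the MVC trials
#'
#' The maximum single-window RMS over all windows, all channels and all
#' (usually three) MVC trials — one scalar per subject, used to normalise
#' every activation map of that subject.
#'
#' @param mvc_recs List of preprocessed MVC [emg_recording()]s.
#' @param window_s RMS window length in seconds.
#' @return `rms_max` in mV.
#' @export
mvc_rms_max <- function(mvc_recs, window_s = 0.2) {
  if (length(mvc_recs) == 0)
    stop("missing data: no MVC trial available")
  best <- 0
  for (rec in mvc_recs) {
    stopifnot(inherits(rec, "emg_recording"))
    N <- round(window_s * rec$fs_hz)
    M <- nrow(rec$signals) %/% N
    if (M < 1) next
    best <- max(best, .window_rms_matrix(rec$signals, N, M))
  }
  if (best <= 0) stop("missing data: MVC trials contain no full RMS window")
  best
}

#' Build an nRMS activation map
#'
#' Divides the windowed RMS grid by the subject's `rms_max`, yielding the
#' dimensionless normalised-RMS (nRMS) activation map on the 8 x 8 grid.
#'
#' @param rms An `rms_grid` from [windowed_rms()].
#' @param rms_max Scalar from [mvc_rms_max()]; must be positive.
#' @param subject_id Subject identifier.
#' @param task Task label or derived label string (`"passive_avg"`,
#'   `"active_avg"`).
#' @return An `activation_map`.
#' @export
build_map <- function(rms, rms_max, subject_id = NA_character_, task = NULL) {
  if (!is.numeric(rms_max) || length(rms_max) != 1 || rms_max <= 0)
    stop("normalization error: rms_max must be a positive scalar")
  values <- rms$values / rms_max
  activation_map(values, subject_id = subject_id, task = task)
}

#' @rdname build_map
#' @param values 8 x 8 non-negative matrix of nRMS values.
#' @param baseline_subtracted Whether the resting-baseline map has been
#'   subtracted.
#' @export
activation_map <- function(values, subject_id = NA_character_, task = NULL,
                           baseline_subtracted = FALSE) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  structure(list(values = values, subject_id = subject_id, task = task,
                 baseline_subtracted = baseline_subtracted),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  lab <- if (inherits(x$task, "task_label")) task_id(x$task) else as.character(x$task)
  cat(sprintf("<activation_map> %s %s%s: mean %.4f, max %.4f\n",
              x$subject_id, lab,
              if (x$baseline_subtracted) " (baseline-subtracted)" else "",
              mean(x$values), max(x$values)))
  invisible(x)
}

#' Subtract the resting baseline map
#'
#' The 10 deg/s stretch does not elicit a reflex and is taken as the
#' subject's resting-state map; subtracting it isolates task-related
#' activity. Negative differences are clamped to zero.
#'
#' @param map,baseline [activation_map()]s of the same subject.
#' @return Baseline-subtracted `activation_map`.
#' @export
subtract_baseline <- function(map, baseline) {
  stopifnot(inherits(map, "activation_map"), inherits(baseline, "activation_map"))
  if (!is.na(map$subject_id) && !is.na(baseline$subject_id) &&
      map$subject_id != baseline$subject_id)
    stop("pairing error: baseline map belongs to a different subject")
  out <- map
  out$values <- pmax(map$values - baseline$values, 0)
  out$baseline_subtracted <- TRUE
  out
}

#' Average activation maps
#'
#' Element-wise mean of maps of the same subject (e.g. the three stretch
#' velocities averaged as the "passive stretch" map, or the three
#' contraction levels as the "active contraction" map).
#'
#' @param maps Non-empty list of [activation_map()]s.
#' @param label Derived task label for the result.
#' @return An `activation_map`.
#' @export
average_maps <- function(maps, label = "avg") {
  if (length(maps) == 0) stop("missing data: no maps to average")
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  activation_map(vals, subject_id = maps[[1]]$subject_id, task = label,
                 baseline_subtracted = maps[[1]]$baseline_subtracted)
}

#' Mean map intensity
#'
#' Arithmetic mean of the 64 original nRMS values — the global activity
#' summary compared across groups and tasks.
#'
#' @param map An [activation_map()].
#' @return Scalar mean nRMS.
#' @export
mean_intensity <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  mean(map$values)
}

#' Upsample a map for display
#'
#' Cubic-spline interpolation from 8 x 8 to `size` x `size` (71 by
#' convention), applied separably along rows then columns. Display only: all
#' statistics (CoG, segmentation, intensities) use the original 8 x 8
#' values.
#'
#' @param map An [activation_map()] or an 8 x 8 matrix.
#' @param size Output side length.
#' @return `size` x `size` numeric matrix.
#' @export
upsample_for_display <- function(map, size = 71L) {
  v <- if (inherits(map, "activation_map")) map$values else map
  xo <- seq(1, ncol(v), length.out = size)
  tmp <- t(apply(v, 1L, function(row)
    stats::spline(seq_len(ncol(v)), row, xout = xo, method = "fmm")$y))
  yo <- seq(1, nrow(v), length.out = size)
  apply(tmp, 2L, function(col)
    stats::spline(seq_len(nrow(v)), col, xout = yo, method = "fmm")$y)
}
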