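#' Detect bad channels
#'
#' Automated surrogate for visual quality inspection: a channel is flagged if
#' its RMS is below `flat_eps` (flatlined / disconnected) or if its log-RMS
#' deviates from the level of its grid neighbourhood by more than `z_thresh`
#' z-scores. The z-score is computed on the *spatial residual* — each
#' channel's log-RMS minus the mean log-RMS of its valid 4-neighbours —
#' rather than on raw log-RMS: poor electrode-skin contact is a
#' single-electrode phenomenon that makes one channel jump out of an
#' otherwise smooth amplitude field, whereas genuine focal activation
#' elevates whole neighbourhoods and must not be flagged.
#'
#' @param rec A filtered [emg_recording()].
#' The residual scale is estimated robustly (MAD) but floored at
#' `scale_floor` log units: on very clean, spatially smooth recordings the
#' empirical roughness approaches the RMS sampling error and any genuine
#' activation peak would otherwise look like an outlier. A contact artifact
#' changes channel amplitude by integer factors (log residual >> 1), so the
#' floor costs no sensitivity.
#'
#' @param z_thresh z-score threshold on the spatial log-RMS residual
#'   (default 3).
#' @param flat_eps RMS floor in mV below which a channel counts as flat.
#' @param scale_floor Minimum assumed residual scale (natural-log units).
#' @return Logical length-64 vector, TRUE = bad.
#' @export
detect_bad_channels <- function(rec, z_thresh = 3, flat_eps = 1e-4,
                                scale_floor = 0.15) {
  stopifnot(inherits(rec, "emg_recording"))
  grid <- rec$grid
  rms <- sqrt(colMeans(rec$signals^2))
  flat <- rms < flat_eps
  bad <- flat
  if (sum(!flat) >= 6) {
    lr <- rep(NA_real_, 64)
    lr[!flat] <- log(rms[!flat])
    # flag one channel at a time (worst first) and drop it from the
    # neighbour means before re-testing: a gross outlier would otherwise
    # corrupt the residuals of its own neighbours
    repeat {
      resid <- .spatial_residual(lr, grid)
      use <- !bad & is.finite(resid)
      if (sum(use) < 6) break
      s <- max(stats::mad(resid[use]), scale_floor)
      z <- abs(resid - stats::median(resid[use])) / s
      worst <- which(use)[which.max(z[use])]
      if (length(worst) == 0 || z[worst] <= z_thresh) break
      bad[worst] <- TRUE
      lr[worst] <- NA_real_
      if (sum(bad) > 20) break
    }
  }
  if (sum(bad) > 20)
    stop("quality error: more than 20 bad channels, recording unusable")
  bad
}

# per-channel log-RMS minus the mean over its valid 4-neighbours
.spatial_residual <- function(lr, grid) {
  lr_mat <- channels_to_matrix(lr, grid)
  nb_sum <- matrix(0, grid$n_rows, grid$n_cols)
  nb_n <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_len(nrow(.neigh4))) {
    di <- .neigh4[k, "di"]; dj <- .neigh4[k, "dj"]
    src_i <- max(1, 1 - di):min(grid$n_rows, grid$n_rows - di)
    src_j <- max(1, 1 - dj):min(grid$n_cols, grid$n_cols - dj)
    sh <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    sh[src_i + di, src_j + dj] <- lr_mat[src_i, src_j]
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_n <- nb_n + ok
  }
  matrix_to_channels(lr_mat - nb_sum / pmax(nb_n, 1), grid)
}

#' Replace bad channels by grid interpolation
#'
#' Each bad channel is replaced, sample-wise, by the mean of its valid
#' 4-neighbours on the electrode grid ("adjacent channels"). Channels with no
#' valid neighbour are filled in later passes once their neighbours have been
#' reconstructed (nearest-first); if a pass fills nothing while bad channels
#' remain, the region is unrecoverable and an error is raised. The
#' `effective_mask` records which channels were synthesised (they stay
#' FALSE, so trial selection can prefer recordings with more genuine
#' channels).
#'
#' @param rec An [emg_recording()].
#' @param bad Logical length-64 mask from [detect_bad_channels()].
#' @return The recording with bad channels replaced and mask updated.
#' @export
interpolate_bad_channels <- function(rec, bad) {
  stopifnot(inherits(rec, "emg_recording"), length(bad) == 64L)
  if (!any(bad)) return(rec)
  grid <- rec$grid
  good <- !bad
  x <- rec$signals
  remaining <- which(bad)
  while (length(remaining) > 0) {
    filled_this_pass <- integer(0)
    for (ch in remaining) {
      rc <- channel_to_grid(ch - 1L, grid)
      ni <- rc[1, "i"] + .neigh4[, "di"]
      nj <- rc[1, "j"] + .neigh4[, "dj"]
      ok <- ni >= 1 & ni <= grid$n_rows & nj >= 1 & nj <= grid$n_cols
      nb <- grid_to_channel(ni[ok], nj[ok], grid) + 1L
      nb <- nb[good[nb]]
      if (length(nb) == 0) next
      avg <- rowMeans(x[, nb, drop = FALSE])
      # rescale to the neighbours' mean RMS: averaging attenuates whatever
      # part of the neighbour signals is uncorrelated, which would leave an
      # amplitude hole at the synthesised channel
      target <- mean(sqrt(colMeans(x[, nb, drop = FALSE]^2)))
      actual <- sqrt(mean(avg^2))
      if (actual > 0) avg <- avg * (target / actual)
      x[, ch] <- avg
      filled_this_pass <- c(filled_this_pass, ch)
    }
    if (length(filled_this_pass) == 0)
      stop("unrecoverable region: bad channels with no valid neighbours")
    good[filled_this_pass] <- TRUE
    remaining <- setdiff(remaining, filled_this_pass)
  }
  rec$signals <- x
  rec$effective_mask <- rec$effective_mask & !bad
  rec
}

#' Filter, detect and interpolate in one step
#'
#' Convenience wrapper running [apply_filters()], [detect_bad_channels()] and
#' [interpolate_bad_channels()] with the given configuration.
#'
#' @param rec An [emg_recording()].
#' @param config A [pipeline_config()].
#' @return Preprocessed recording.
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  rec <- apply_filters(rec, config$filter)
  bad <- detect_bad_channels(rec, config$z_thresh, config$flat_eps)
  interpolate_bad_channels(rec, bad)
}
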