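# fixtures and independent oracles used across the suite

# recording whose 64 channels all carry the same deterministic trace
const_recording <- function(value = 1, n = 800, fs = 2000,
                            task = task_label("mvc"), aux = NULL) {
  emg_recording(matrix(value, n, 64), fs, task, aux = aux, subject_id = "T")
}

trace_recording <- function(trace, fs = 2000, task = task_label("mvc"),
                            aux = NULL) {
  emg_recording(matrix(trace, length(trace), 64), fs, task, aux = aux,
                subject_id = "T")
}

# map with given cells set (list of c(i, j, value)) on a zero background
point_map <- function(..., base = 0) {
  v <- matrix(base, 8, 8)
  for (cell in list(...)) v[cell[1], cell[2]] <- cell[3]
  activation_map(v, subject_id = "T", task = "test")
}

mask_from_cells <- function(cells) {
  m <- matrix(FALSE, 8, 8)
  for (cell in cells) m[cell[1], cell[2]] <- TRUE
  cluster_mask(m)
}

# naive grayscale reconstruction oracle: per-pixel fixed-point iteration,
# deliberately scalar (independent of the vectorised implementation)
naive_reconstruct <- function(marker, mask, connectivity = 8) {
  offs <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- marker
  repeat {
    nxt <- cur
    for (i in 1:nrow(cur)) for (j in 1:ncol(cur)) {
      best <- cur[i, j]
      for (k in 1:nrow(offs)) {
        ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
        if (ii >= 1 && ii <= nrow(cur) && jj >= 1 && jj <= ncol(cur))
          best <- max(best, cur[ii, jj])
      }
      nxt[i, j] <- min(best, mask[i, j])
    }
    if (all(nxt == cur)) return(nxt)
    cur <- nxt
  }
}

naive_hdome <- function(v, h, connectivity = 8) {
  v - naive_reconstruct(v - h, v, connectivity)
}

# mixed-design ANOVA oracle through stats::aov with an Error() stratum
aov_mixed_oracle <- function(values, group) {
  n <- nrow(values); k <- ncol(values)
  df <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    task = factor(rep(seq_len(k), each = n)),
    group = factor(rep(group, times = k)))
  fit <- summary(stats::aov(y ~ group * task + Error(subject), data = df))
  s1 <- fit[["Error: subject"]][[1]]
  s2 <- fit[["Error: Within"]][[1]]
  list(F_group = s1["group", "F value"],
       F_task = s2["task", "F value"],
       F_int = s2["group:task", "F value"])
}

aov_rm_oracle <- function(values) {
  n <- nrow(values); k <- ncol(values)
  df <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    task = factor(rep(seq_len(k), each = n)))
  fit <- summary(stats::aov(y ~ task + Error(subject), data = df))
  fit[["Error: Within"]][[1]]["task", "F value"]
}

# synthetic subject with one voluntary blob on a near-zero floor, used for
# CoG parameter-recovery checks
single_blob_subject <- function(ci, cj, id = "X") {
  structure(list(
    subject_id = id, group = "spastic",
    mvc_amplitude_mv = 0.5, mvc_force_n = 180,
    active_profile = spatial_profile(
      data.frame(ci = ci, cj = cj, si = 1.2, sj = 1.2, gain = 0.95),
      floor_gain = 0.05),
    passive_profile = spatial_profile(
      data.frame(ci = 4.5, cj = 4.5, si = 2, sj = 2, gain = 1e-9),
      floor_gain = 1),
    force_emg_exponent = 1, baseline_tone = 0.01,
    reflex_rel = c("60" = 0, "120" = 0, "180" = 0),
    line_noise_mv = 0.02, sensor_noise_mv = 0.002, trial_jitter_sd = 0,
    bad_channels = integer(0), bad_channel_flat = logical(0)),
    class = "subject_model")
}
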