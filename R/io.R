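#' Dataset input/output
#'
#' Datasets are plain-text directories: a `manifest.json` at the root, one
#' sub-directory per subject, and per recording a CSV signal table (columns
#' `ch00..ch63` in mV, plus an optional `aux` column: joint angle in degrees
#' for passive trials, force in N for active/MVC trials; one row per sample)
#' with a JSON sidecar `<name>.meta.json` carrying the sampling rate, task
#' label, grid mapping and effective-channel mask. There is no public
#' amplifier format for HD-sEMG grids; this layout keeps datasets
#' readable, diffable and desk-scale testable.
#'
#' @name dataset_io
NULL

.rec_filename <- function(task) sprintf("%s_%d", task_id(task), task$trial)

.write_recording <- function(dir, name, rec) {
  # columns are formatted with %.17g so that doubles survive the text
  # round-trip bit-exactly
  fmt <- function(x) sprintf("%.17g", x)
  sig <- rec$signals
  df <- data.table::as.data.table(
    `colnames<-`(matrix(fmt(sig), nrow(sig), ncol(sig)),
                 sprintf("ch%02d", 0:63)))
  if (!is.null(rec$aux)) df[["aux"]] <- fmt(rec$aux)
  data.table::fwrite(df, file.path(dir, paste0(name, ".csv")), quote = FALSE)
  meta <- list(
    fs_hz = rec$fs_hz,
    kind = rec$task$kind,
    level = rec$task$level,
    trial = rec$task$trial,
    subject_id = rec$subject_id,
    grid = list(n_rows = rec$grid$n_rows, n_cols = rec$grid$n_cols,
                ied_mm = rec$grid$ied_mm,
                mapping = "row-major: channel k -> (i = k %/% 8 + 1, j = k %% 8 + 1)"),
    effective_channels = which(rec$effective_mask) - 1L,
    aux_kind = if (is.null(rec$aux)) NA_character_
               else if (rec$task$kind == "passive") "angle_deg" else "force_n")
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".meta.json")),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

.read_recording <- function(dir, name) {
  meta_path <- file.path(dir, paste0(name, ".meta.json"))
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e)
                     stop(sprintf("format error in metadata sidecar '%s': %s",
                                  meta_path, conditionMessage(e))))
  need <- c("fs_hz", "kind", "trial")
  if (!all(need %in% names(meta)))
    stop(sprintf("format error in metadata sidecar '%s': missing %s",
                 meta_path, paste(setdiff(need, names(meta)), collapse = ", ")))
  df <- data.table::fread(file.path(dir, paste0(name, ".csv")))
  ch_cols <- grep("^ch[0-9]{2}$", names(df), value = TRUE)
  if (length(ch_cols) != 64)
    stop(sprintf("geometry error: '%s' has %d signal columns, expected 64",
                 file.path(dir, paste0(name, ".csv")), length(ch_cols)))
  sig <- as.matrix(df[, ch_cols, with = FALSE])
  dimnames(sig) <- NULL
  aux <- if ("aux" %in% names(df)) as.numeric(df[["aux"]]) else NULL
  lvl <- if (is.null(meta$level) || is.na(meta$level)) NA_real_
         else as.numeric(meta$level)
  task <- task_label(meta$kind, lvl, meta$trial)
  mask <- rep(FALSE, 64)
  mask[unlist(meta$effective_channels) + 1L] <- TRUE
  emg_recording(sig, meta$fs_hz, task, aux = aux, effective_mask = mask,
                subject_id = meta$subject_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.init_dataset_dir <- function(path, seed) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("I/O error: cannot create '%s'", path))
  invisible(path)
}

.write_subject_recordings <- function(path, subject_id, recs) {
  sdir <- file.path(path, subject_id)
  dir.create(sdir, showWarnings = FALSE)
  for (nm in names(recs))
    .write_recording(sdir, .rec_filename(recs[[nm]]$task), recs[[nm]])
  invisible(sdir)
}

.serialize_model <- function(m) {
  list(subject_id = m$subject_id, group = m$group,
       mvc_amplitude_mv = m$mvc_amplitude_mv, mvc_force_n = m$mvc_force_n,
       active_profile = list(blobs = m$active_profile$blobs,
                             floor_gain = m$active_profile$floor_gain),
       passive_profile = list(blobs = m$passive_profile$blobs,
                              floor_gain = m$passive_profile$floor_gain),
       force_emg_exponent = m$force_emg_exponent,
       baseline_tone = m$baseline_tone,
       reflex_rel = as.list(m$reflex_rel),
       line_noise_mv = m$line_noise_mv,
       sensor_noise_mv = m$sensor_noise_mv,
       bad_channels = m$bad_channels,
       bad_channel_flat = m$bad_channel_flat)
}

.finalize_manifest <- function(path, subjects, seed, subject_seeds = NULL) {
  manifest <- list(
    format = "spasmap-dataset",
    version = 1L,
    seed = seed,
    subject_seeds = subject_seeds,
    subjects = lapply(subjects, function(s)
      if (inherits(s, "subject_model")) .serialize_model(s) else s))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write a cohort of recordings to a dataset directory
#'
#' @param cohort List with `recordings` (named list: subject id -> named list
#'   of [emg_recording()]s) and `groups` (named character vector); the
#'   structure returned by [simulate_cohort()] with `path = NULL`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @seealso [dataset_io]
#' @export
write_dataset <- function(cohort, path) {
  .init_dataset_dir(path, cohort$seed %||% NA_integer_)
  for (id in names(cohort$recordings))
    .write_subject_recordings(path, id, cohort$recordings[[id]])
  subjects <- cohort$subjects
  if (is.null(subjects))
    subjects <- lapply(names(cohort$recordings), function(id)
      list(subject_id = id, group = unname(cohort$groups[id])))
  .finalize_manifest(path, subjects, cohort$seed %||% NA_integer_)
  invisible(path)
}

#' Read a dataset directory into a cohort
#'
#' Loads every subject's recordings and checks trial completeness (3 MVC,
#' 3 x 4 passive, 3 x 3 active per subject); subjects with missing trials
#' are loaded with a warning and flagged in `incomplete`.
#'
#' @param path Dataset directory written by [write_dataset()] or
#'   [simulate_cohort()].
#' @return List with `recordings`, `groups`, `incomplete` and `manifest`.
#' @seealso [dataset_io]
#' @export
read_dataset <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path))
    stop(sprintf("format error: no manifest.json in '%s'", path))
  manifest <- tryCatch(jsonlite::read_json(man_path),
                       error = function(e)
                         stop(sprintf("format error in '%s': %s", man_path,
                                      conditionMessage(e))))
  subj_dirs <- list.dirs(path, full.names = FALSE, recursive = FALSE)
  recordings <- list()
  groups <- character(0)
  incomplete <- character(0)
  man_groups <- vapply(manifest$subjects, function(s) s$group %||% NA_character_,
                       character(1))
  man_ids <- vapply(manifest$subjects, function(s) s$subject_id %||% NA_character_,
                    character(1))
  for (id in subj_dirs) {
    sdir <- file.path(path, id)
    csvs <- sort(list.files(sdir, pattern = "\\.csv$"))
    names_ <- sub("\\.csv$", "", csvs)
    recs <- stats::setNames(lapply(names_, function(nm) .read_recording(sdir, nm)),
                            names_)
    recordings[[id]] <- recs
    groups[id] <- if (id %in% man_ids) man_groups[match(id, man_ids)] else NA_character_
    kinds <- vapply(recs, function(r) r$task$kind, character(1))
    ok <- sum(kinds == "mvc") == 3 && sum(kinds == "passive") == 12 &&
          sum(kinds == "active") == 9
    if (!ok) {
      warning(sprintf("subject %s has missing trials (%d recordings); flagged",
                      id, length(recs)))
      incomplete <- c(incomplete, id)
    }
  }
  list(recordings = recordings, groups = groups, incomplete = incomplete,
       manifest = manifest)
}
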