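#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default. The
#' baseline policy controls which maps have the subject's resting (10 deg/s)
#' map subtracted before CoG extraction and segmentation: `"cog_all"`
#' (default) subtracts it from both passive and active maps, `"cog_passive_only"`
#' only from the passive maps, `"none"` disables subtraction. Mean map
#' intensities are always reported from the unsubtracted maps.
#'
#' @param filter A [filter_settings()].
#' @param window_s RMS window length (s).
#' @param seg A [segmentation_settings()].
#' @param baseline_scope One of `"cog_all"`, `"cog_passive_only"`, `"none"`.
#' @param z_thresh,flat_eps Bad-channel detection thresholds (see
#'   [detect_bad_channels()]).
#' @param vel_on_frac Passive epoch onset threshold (fraction of nominal
#'   velocity).
#' @param active_window_s Active epoch length (s).
#' @param welch,gg_correction Statistics options (Welch t-test /
#'   Greenhouse-Geisser correction), both off by default.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(filter = filter_settings(), window_s = 0.2,
                            seg = segmentation_settings(),
                            baseline_scope = c("cog_all", "cog_passive_only", "none"),
                            z_thresh = 3, flat_eps = 1e-4,
                            vel_on_frac = 0.5, active_window_s = 3,
                            welch = FALSE, gg_correction = FALSE) {
  baseline_scope <- match.arg(baseline_scope)
  structure(list(filter = filter, window_s = window_s, seg = seg,
                 baseline_scope = baseline_scope, z_thresh = z_thresh,
                 flat_eps = flat_eps, vel_on_frac = vel_on_frac,
                 active_window_s = active_window_s, welch = welch,
                 gg_correction = gg_correction),
            class = "pipeline_config")
}

.passive_velocities <- c(10, 60, 120, 180)
.active_levels <- c(0.2, 0.5, 0.8)

#' Analyse one subject's recordings
#'
#' Runs the per-subject chain: preprocessing (filters, bad-channel
#' detection/interpolation), MVC normalisation constant, epoch extraction
#' and trial selection per condition, nRMS activation maps, baseline
#' subtraction, CoG, segmentation into relevant channels, and within- and
#' between-task overlap degrees.
#'
#' @param recs Named list of the subject's [emg_recording()]s (full
#'   protocol).
#' @param config A [pipeline_config()].
#' @param group Group label carried into the result.
#' @return A `subject_result` list.
#' @export
analyze_subject <- function(recs, config = pipeline_config(), group = NA_character_) {
  recs <- lapply(recs, preprocess_recording, config = config)
  kinds <- vapply(recs, function(r) r$task$kind, character(1))
  subject_id <- recs[[1]]$subject_id

  rms_max <- mvc_rms_max(recs[kinds == "mvc"], config$window_s)

  cond_map <- function(kind, level) {
    sel <- which(kinds == kind &
                 vapply(recs, function(r) isTRUE(all.equal(r$task$level, level)),
                        logical(1)))
    if (length(sel) == 0)
      stop(sprintf("missing data: no %s trials at level %g for %s",
                   kind, level, subject_id))
    eps <- lapply(recs[sel], function(r) {
      if (kind == "passive")
        extract_passive_stretch_epoch(r, config$vel_on_frac)
      else
        extract_active_epoch(r, config$active_window_s)
    })
    ep <- select_trial_epoch(eps)
    build_map(windowed_rms(ep, config$window_s), rms_max,
              subject_id = subject_id, task = ep$task)
  }

  passive_maps <- lapply(.passive_velocities, function(v) cond_map("passive", v))
  names(passive_maps) <- sprintf("passive_%03d", .passive_velocities)
  active_maps <- lapply(.active_levels, function(l) cond_map("active", l))
  names(active_maps) <- sprintf("active_%02d", round(.active_levels * 100))

  intensities <- vapply(c(passive_maps, active_maps), mean_intensity, numeric(1))

  baseline <- passive_maps[["passive_010"]]
  sub_if <- function(m, is_passive) {
    if (config$baseline_scope == "none") return(m)
    if (config$baseline_scope == "cog_passive_only" && !is_passive) return(m)
    subtract_baseline(m, baseline)
  }
  passive_sub <- lapply(passive_maps[-1], sub_if, is_passive = TRUE)
  active_sub <- lapply(active_maps, sub_if, is_passive = FALSE)

  safe_cog <- function(m) {
    tryCatch(cog(m), error = function(e) {
      warning(sprintf("%s %s: %s", subject_id,
                      if (inherits(m$task, "task_label")) task_id(m$task)
                      else as.character(m$task), conditionMessage(e)))
      list(i = NA_real_, j = NA_real_)
    })
  }
  passive_cogs <- lapply(passive_sub, safe_cog)
  active_cogs <- lapply(active_sub, safe_cog)

  passive_masks <- lapply(passive_sub, segment_relevant_channels, settings = config$seg)
  active_masks <- lapply(active_sub, segment_relevant_channels, settings = config$seg)

  passive_avg <- average_maps(passive_sub, "passive_avg")
  active_avg <- average_maps(active_sub, "active_avg")
  passive_avg_mask <- segment_relevant_channels(passive_avg, config$seg)
  active_avg_mask <- segment_relevant_channels(active_avg, config$seg)

  structure(list(
    subject_id = subject_id, group = group, rms_max = rms_max,
    intensities = intensities,
    passive_maps = passive_maps, active_maps = active_maps,
    passive_cogs = passive_cogs, active_cogs = active_cogs,
    passive_masks = passive_masks, active_masks = active_masks,
    passive_avg = passive_avg, active_avg = active_avg,
    passive_avg_mask = passive_avg_mask, active_avg_mask = active_avg_mask,
    within_passive = within_task_overlap(passive_masks),
    within_active = within_task_overlap(active_masks),
    between_tasks = between_task_overlap(passive_avg_mask, active_avg_mask)),
    class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s (%s): RMSmax %.3f mV, within P/A %.1f/%.1f%%, between %.1f%%\n",
              x$subject_id, x$group, x$rms_max,
              x$within_passive, x$within_active, x$between_tasks))
  invisible(x)
}

# tidy per-subject tables ---------------------------------------------------

.intensity_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(subject_id = r$subject_id, group = r$group,
               task = names(r$intensities),
               intensity = unname(r$intensities),
               row.names = NULL, stringsAsFactors = FALSE)))
}

.cog_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    cogs <- c(r$passive_cogs, r$active_cogs)
    data.frame(subject_id = r$subject_id, group = r$group,
               task = names(cogs),
               i = vapply(cogs, `[[`, numeric(1), "i"),
               j = vapply(cogs, `[[`, numeric(1), "j"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

.overlap_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(subject_id = r$subject_id, group = r$group,
               within_passive = r$within_passive,
               within_active = r$within_active,
               between_tasks = r$between_tasks,
               row.names = NULL, stringsAsFactors = FALSE)))
}

# subject x task intensity matrix for a group and task family
.intensity_matrix <- function(results, tasks) {
  t(vapply(results, function(r) unname(r$intensities[tasks]),
           numeric(length(tasks))))
}

#' Group-level statistics of a cohort
#'
#' Reproduces the study's statistical layer on the per-subject results:
#' mixed two-way repeated-measures ANOVA (group x task) on the mean map
#' intensities of the passive and active families, post hoc
#' independent-samples t-tests per task, one-way repeated-measures ANOVA
#' within each group, independent t-tests on the active CoG coordinates
#' between groups, and paired t-tests on passive vs active CoG coordinates
#' within the spastic group. No multiple-comparison correction is applied
#' (the post hoc structure is replicated literally).
#'
#' @param results List of `subject_result`s.
#' @param config A [pipeline_config()].
#' @return A `cohort_result` list of tables.
#' @export
cohort_statistics <- function(results, config = pipeline_config()) {
  grp <- vapply(results, `[[`, character(1), "group")
  spast <- results[grp == "spastic"]
  healthy <- results[grp == "healthy"]
  ptasks <- sprintf("passive_%03d", .passive_velocities)
  atasks <- sprintf("active_%02d", round(.active_levels * 100))

  anova_tabs <- list(); oneway_tabs <- list(); ttests <- list()
  for (fam in list(list(name = "passive", tasks = ptasks),
                   list(name = "active", tasks = atasks))) {
    vals <- .intensity_matrix(results, fam$tasks)
    anova_tabs[[fam$name]] <- cbind(family = fam$name,
      mixed_anova(vals, grp, gg_correction = config$gg_correction))
    for (g in c("healthy", "spastic")) {
      oneway_tabs[[paste(fam$name, g, sep = "_")]] <- cbind(
        family = fam$name, group = g,
        one_way_rm_anova(.intensity_matrix(results[grp == g], fam$tasks)))
    }
    for (task in fam$tasks) {
      a <- vapply(spast, function(r) unname(r$intensities[task]), numeric(1))
      b <- vapply(healthy, function(r) unname(r$intensities[task]), numeric(1))
      ttests[[task]] <- t_independent(a, b, welch = config$welch,
        label = sprintf("intensity %s: spastic vs healthy", task))
    }
  }

  cog_active <- function(rs, coord)
    vapply(rs, function(r)
      mean(vapply(r$active_cogs, `[[`, numeric(1), coord)), numeric(1))
  cog_passive <- function(rs, coord)
    vapply(rs, function(r)
      mean(vapply(r$passive_cogs, `[[`, numeric(1), coord)), numeric(1))

  cog_tests <- rbind(
    t_independent(cog_active(spast, "i"), cog_active(healthy, "i"),
                  welch = config$welch,
                  label = "active CoG i: spastic vs healthy"),
    t_independent(cog_active(spast, "j"), cog_active(healthy, "j"),
                  welch = config$welch,
                  label = "active CoG j: spastic vs healthy"),
    t_paired(cog_passive(spast, "i"), cog_active(spast, "i"),
             label = "spastic CoG i: passive vs active (paired)"),
    t_paired(cog_passive(spast, "j"), cog_active(spast, "j"),
             label = "spastic CoG j: passive vs active (paired)"))

  ov <- .overlap_table(results)
  overlap_summary <- data.frame(
    category = c("spastic within passive", "healthy within active",
                 "spastic within active", "spastic between tasks"),
    mean = c(mean(ov$within_passive[ov$group == "spastic"], na.rm = TRUE),
             mean(ov$within_active[ov$group == "healthy"], na.rm = TRUE),
             mean(ov$within_active[ov$group == "spastic"], na.rm = TRUE),
             mean(ov$between_tasks[ov$group == "spastic"], na.rm = TRUE)),
    sd = c(stats::sd(ov$within_passive[ov$group == "spastic"], na.rm = TRUE),
           stats::sd(ov$within_active[ov$group == "healthy"], na.rm = TRUE),
           stats::sd(ov$within_active[ov$group == "spastic"], na.rm = TRUE),
           stats::sd(ov$between_tasks[ov$group == "spastic"], na.rm = TRUE)),
    stringsAsFactors = FALSE)

  structure(list(
    subject_results = results,
    intensity = .intensity_table(results),
    cog = .cog_table(results),
    overlap = ov,
    overlap_summary = overlap_summary,
    anova = do.call(rbind, anova_tabs),
    oneway = do.call(rbind, oneway_tabs),
    t_intensity = do.call(rbind, ttests),
    t_cog = cog_tests),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects (%d spastic, %d healthy)\n",
              nrow(x$overlap), sum(x$overlap$group == "spastic"),
              sum(x$overlap$group == "healthy")))
  cat("overlap summary (%):\n")
  print(x$overlap_summary, row.names = FALSE)
  invisible(x)
}

#' Run the full pipeline
#'
#' End-to-end orchestration: either simulates the default synthetic cohort
#' (subject by subject, bounding memory) or loads a dataset directory, then
#' analyses every subject and computes the group statistics. Fully
#' reproducible given `seed`.
#'
#' @param simulate `NULL`, or a list with `n_spastic`, `n_healthy`, `seed`
#'   controlling cohort simulation.
#' @param dataset Path to a dataset directory (used when `simulate` is
#'   `NULL`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory to which result tables are written as
#'   CSV plus a JSON summary.
#' @param progress Print one line per subject.
#' @return A `cohort_result`.
#' @export
run_pipeline <- function(simulate = list(n_spastic = 14, n_healthy = 10, seed = 1),
                         dataset = NULL, config = pipeline_config(),
                         out_dir = NULL, progress = FALSE) {
  results <- list()
  if (!is.null(simulate)) {
    set.seed(simulate$seed)
    groups <- c(rep("spastic", simulate$n_spastic),
                rep("healthy", simulate$n_healthy))
    ids <- c(sprintf("S%02d", seq_len(simulate$n_spastic)),
             sprintf("H%02d", seq_len(simulate$n_healthy)))
    subject_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
    for (k in seq_along(ids)) {
      set.seed(subject_seeds[k])
      subj <- make_subject(groups[k], subject_id = ids[k])
      recs <- simulate_subject_recordings(subj)
      results[[ids[k]]] <- analyze_subject(recs, config, group = groups[k])
      if (progress) print(results[[ids[k]]])
      rm(recs)
    }
  } else {
    if (is.null(dataset)) stop("config error: need either simulate or dataset")
    cohort <- read_dataset(dataset)
    for (id in names(cohort$recordings)) {
      results[[id]] <- tryCatch(
        analyze_subject(cohort$recordings[[id]], config,
                        group = cohort$groups[[id]]),
        error = function(e) stop(sprintf("stage analyze[%s]: %s", id,
                                         conditionMessage(e))))
      if (progress) print(results[[id]])
    }
  }
  res <- cohort_statistics(results, config)
  if (!is.null(out_dir)) export_results(res, out_dir)
  res
}

#' Export cohort result tables
#'
#' Writes the intensity, CoG, overlap and statistics tables as CSV and a
#' JSON summary mirroring the cohort result.
#'
#' @param res A `cohort_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  w(res$intensity, "intensity")
  w(res$cog, "cog")
  w(res$overlap, "overlap")
  w(res$overlap_summary, "overlap_summary")
  w(res$anova, "anova")
  w(res$oneway, "oneway_anova")
  w(res$t_intensity, "t_intensity")
  w(res$t_cog, "t_cog")
  summary <- list(
    overlap_summary = res$overlap_summary,
    anova = res$anova,
    t_cog = res$t_cog)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out_dir)
}
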