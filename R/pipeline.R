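#' Estimate strides from one IMU file
#'
#' Reads the recording, detects still periods, estimates per-stride
#' speeds and writes the stride table CSV. Logs the sample, still and
#' stride counts at verbosity >= 1.
#'
#' @param imu_path input IMU CSV.
#' @param out output stride CSV.
#' @param config configuration list, see [default_config()].
#' @param subject,trial labels stamped on the output rows.
#' @return the stride table, invisibly.
#' @export
run_estimate <- function(imu_path, out, config = default_config(),
                         subject = "unknown", trial = "") {
  rec <- read_imu(imu_path, accel_unit = config$io$accel_unit,
                  gyro_unit = config$io$gyro_unit,
                  fs_hint = config$io$fs_hint, subject_id = subject)
  params <- config_stride_params(config)
  mask <- detect_still(rec, params$gyro_thresh, params$accel_band,
                       params$min_still)
  strides <- estimate_strides(rec, mask, params)
  if (config$verbosity >= 1)
    message(sprintf("%s: %d samples, %d still intervals, %d strides",
                    imu_path, n_samples(rec), nrow(mask$intervals),
                    nrow(strides)))
  write_strides(strides, out, subject = subject, trial = trial)
  invisible(strides)
}

#' Analyze a cohort: bouts, states, summaries and the lab-vs-home grid
#'
#' @param manifest data.frame (or CSV path) with columns `subject`,
#'   `strides_csv` and optionally `diary_csv` (empty or NA when no diary
#'   was kept: all of that subject's time stays unlabeled).
#' @param lab_csv CSV of lab results: `subject`, `task`, `med_state`,
#'   `mean_speed`.
#' @param out_dir output directory: per-subject bout tables, the
#'   summaries table and the report (JSON + CSV) are written there.
#' @param config configuration list.
#' @param clinical_csv optional clinical-scores CSV.
#' @return the `cohort_result`, invisibly.
#' @export
run_analyze <- function(manifest, lab_csv, out_dir,
                        config = default_config(), clinical_csv = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bcfg <- config$bouts
  summaries <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject[i]
    strides <- read_strides(manifest$strides_csv[i])
    diary_path <- if ("diary_csv" %in% names(manifest))
      manifest$diary_csv[i] else NA
    if (!is.na(diary_path) && nzchar(diary_path)) {
      diary <- read_diary(diary_path)
      diary$time <- diary$time + config$io$diary_offset_s
      timeline <- build_state_timeline(
        diary, on_window = bcfg$on_window_min * 60,
        noton_window = bcfg$noton_window_min * 60,
        overlap_policy = bcfg$overlap_policy)
    } else {
      warning("subject ", id, ": no diary; all time unlabeled")
      timeline <- build_state_timeline(numeric(0))
    }
    strides <- assign_states(strides, timeline)
    bouts <- assign_states(
      segment_bouts(strides, bcfg$max_gap_s, bcfg$min_speed_ms), timeline)
    if (config$verbosity >= 1) {
      n_slow <- sum(strides$speed < bcfg$min_speed_ms)
      n_short <- sum(bouts$length_class == "excluded_short")
      message(sprintf(
        "%s: %d strides (%d below %.2f m/s), %d bouts (%d shorter than %g s)",
        id, nrow(strides), n_slow, bcfg$min_speed_ms, nrow(bouts), n_short,
        bcfg$min_bout_s))
    }
    utils::write.csv(cbind(subject = id, bouts),
                     file.path(out_dir, paste0("bouts_", id, ".csv")),
                     row.names = FALSE)
    for (state in c("ON", "not_ON"))
      summaries[[length(summaries) + 1L]] <- summarize_subject(
        strides, bouts, state, bcfg$min_speed_ms, subject_id = id)
  }
  home <- home_summary_table(summaries)
  utils::write.csv(home, file.path(out_dir, "home_summaries.csv"),
                   row.names = FALSE)
  lab <- utils::read.csv(lab_csv)
  clinical <- if (!is.null(clinical_csv)) read_clinical_scores(clinical_csv)
  result <- build_cohort_grid(lab, home, clinical,
                              alpha = config$stats$alpha,
                              min_n = config$stats$min_n,
                              mt_correction = config$stats$mt_correction)
  write_report(result, file.path(out_dir, "report"))
  invisible(result)
}

#' Simulate a cohort dataset to disk
#'
#' Writes per-subject stride tables and diaries, the lab results table,
#' the ground-truth parameters and a manifest, in the package's own IO
#' formats, so simulated data is structurally indistinguishable from
#' ingested data.
#'
#' @param out_dir output directory.
#' @param scenario a [cohort_scenario()].
#' @param seed RNG seed (same seed, same dataset).
#' @param config configuration list.
#' @return the manifest data.frame, invisibly.
#' @export
run_simulate <- function(out_dir, scenario = cohort_scenario(),
                         seed = 1, config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- synth_cohort(scenario, seed = seed)
  utils::write.csv(cohort$lab, file.path(out_dir, "lab.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  manifest <- data.frame(subject = names(cohort$home),
                         strides_csv = NA_character_,
                         diary_csv = NA_character_)
  for (i in seq_along(cohort$home)) {
    id <- names(cohort$home)[i]
    day <- cohort$home[[id]]
    spath <- file.path(out_dir, paste0("strides_", id, ".csv"))
    dpath <- file.path(out_dir, paste0("diary_", id, ".csv"))
    st <- day$strides
    write_strides(data.frame(t_start = st$t_start, t_end = st$t_end,
                             duration = st$duration, speed = st$speed,
                             flags = ""),
                  spath, subject = id, trial = "home")
    utils::write.csv(data.frame(timestamp = day$diary$time,
                                dose_label = day$diary$dose_label),
                     dpath, row.names = FALSE)
    manifest$strides_csv[i] <- spath
    manifest$diary_csv[i] <- dpath
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  if (config$verbosity >= 1)
    message(sprintf("simulated %d subjects into %s",
                    scenario$n_subjects, out_dir))
  invisible(manifest)
}
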