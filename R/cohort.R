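#' Flatten per-subject speed summaries to a long table
#'
#' @param summaries list of [summarize_subject()] results (any mix of
#'   subjects and states).
#' @return data.frame with columns `subject`, `state`, `metric`
#'   (`"percentile"` / `"wb"`), `wb_class` (NA for percentiles), `stat`,
#'   `value`.
#' @export
home_summary_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    pc <- data.frame(subject = s$subject_id, state = s$state,
                     metric = "percentile", wb_class = NA_character_,
                     stat = names(s$percentiles),
                     value = unname(s$percentiles))
    wb <- expand.grid(wb_class = rownames(s$wb_stats),
                      stat = colnames(s$wb_stats),
                      stringsAsFactors = FALSE)
    wb <- data.frame(subject = s$subject_id, state = s$state,
                     metric = "wb", wb_class = wb$wb_class, stat = wb$stat,
                     value = s$wb_stats[cbind(wb$wb_class, wb$stat)])
    rbind(pc, wb)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lab-vs-home comparison grid for a cohort
#'
#' Builds the full supervised-vs-unsupervised comparison: for every lab
#' task and every home speed metric (distribution percentiles and
#' walking-bout statistics), subjects' lab means are paired with their
#' home values and compared (normality-gated paired test) and correlated
#' (normality-gated correlation with banding and R-squared). Same-state
#' pairings (lab ON vs home ON; lab OFF vs home not-ON) and
#' opposite-state pairings are both emitted, as are ON-vs-OFF paired
#' comparisons per variable and, when clinical scores are supplied,
#' UPDRS-III total / gait-item correlations against the home percentiles.
#'
#' Fast-pace lab trials in the OFF state are excluded from the grid (too
#' few fluctuating patients can perform them); cells with fewer than
#' `min_n` complete pairs are flagged `insufficient_n` and left NA.
#'
#' @param lab data.frame `subject`, `task`, `med_state`, `mean_speed`.
#' @param home long table from [home_summary_table()].
#' @param clinical optional data.frame from [read_clinical_scores()].
#' @param alpha significance level for normality gates.
#' @param min_n minimum complete pairs per cell.
#' @param mt_correction `"none"` (default) or `"BH"`: optional
#'   Benjamini-Hochberg adjusted p-value columns appended to the grid.
#' @return object of class `cohort_result`: list with `grid`, `on_off`,
#'   `clinical`, `n_subjects`, `settings`.
#' @export
build_cohort_grid <- function(lab, home, clinical = NULL, alpha = 0.05,
                              min_n = 3, mt_correction = c("none", "BH")) {
  mt_correction <- c(match.arg(mt_correction))
  lab <- lab[!(lab$task == "straight_fast" & lab$med_state == "OFF"), ,
             drop = FALSE]
  pairings <- data.frame(
    lab_state = c("ON", "OFF", "ON", "OFF"),
    home_state = c("ON", "not_ON", "not_ON", "ON"),
    grid_type = c("same", "same", "opposite", "opposite"))
  metrics <- unique(home[c("metric", "wb_class", "stat")])
  cells <- list()
  for (p in seq_len(nrow(pairings))) for (task in unique(lab$task)) {
    lab_sub <- lab[lab$task == task & lab$med_state == pairings$lab_state[p], ]
    if (!nrow(lab_sub)) next
    for (m in seq_len(nrow(metrics))) {
      home_sub <- home[home$state == pairings$home_state[p] &
                         home$metric == metrics$metric[m] &
                         (home$metric == "percentile" |
                            home$wb_class %in% metrics$wb_class[m]) &
                         home$stat == metrics$stat[m], ]
      mg <- merge(lab_sub[c("subject", "mean_speed")],
                  home_sub[c("subject", "value")], by = "subject")
      cmp <- paired_compare(mg$mean_speed, mg$value, alpha)
      cr <- correlate_paired(mg$mean_speed, mg$value, alpha)
      n_ok <- sum(!is.na(mg$mean_speed) & !is.na(mg$value))
      flags <- unique(c(cmp$flags, cr$flags,
                        if (n_ok < min_n) "insufficient_n"))
      cells[[length(cells) + 1L]] <- data.frame(
        lab_task = task, lab_state = pairings$lab_state[p],
        home_state = pairings$home_state[p],
        grid_type = pairings$grid_type[p],
        metric = metrics$metric[m], wb_class = metrics$wb_class[m],
        stat = metrics$stat[m], n = n_ok,
        comparison_test = cmp$test_used, comparison_p = cmp$p,
        corr_used = cr$corr_used, r = cr$r, corr_p = cr$corr_p,
        band = cr$band, r2 = cr$r2,
        transform_applied = cr$transform_applied,
        flags = paste(flags, collapse = ","))
    }
  }
  grid <- if (length(cells)) do.call(rbind, cells) else NULL
  if (!is.null(grid)) {
    na_cells <- grid$n < min_n
    grid[na_cells, c("comparison_p", "r", "corr_p", "r2")] <- NA_real_
    if (mt_correction == "BH") {
      grid$comparison_p_adj <- stats::p.adjust(grid$comparison_p, "BH")
      grid$corr_p_adj <- stats::p.adjust(grid$corr_p, "BH")
    }
    rownames(grid) <- NULL
  }

  on_off <- .on_off_comparisons(lab, home, alpha)
  clin <- if (!is.null(clinical)) .clinical_correlations(clinical, home, alpha)
  structure(list(grid = grid, on_off = on_off, clinical = clin,
                 n_subjects = length(unique(c(lab$subject, home$subject))),
                 settings = list(alpha = alpha, min_n = min_n,
                                 mt_correction = mt_correction)),
            class = "cohort_result")
}

# per-variable ON vs OFF (lab) and ON vs not-ON (home) paired comparisons
.on_off_comparisons <- function(lab, home, alpha) {
  rows <- list()
  for (task in unique(lab$task)) {
    w <- merge(lab[lab$task == task & lab$med_state == "ON",
                   c("subject", "mean_speed")],
               lab[lab$task == task & lab$med_state == "OFF",
                   c("subject", "mean_speed")],
               by = "subject", suffixes = c("_on", "_off"))
    cmp <- paired_compare(w$mean_speed_on, w$mean_speed_off, alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      domain = "lab", variable = task, n = cmp$n,
      test_used = cmp$test_used, p = cmp$p,
      flags = paste(cmp$flags, collapse = ","))
  }
  metrics <- unique(home[c("metric", "wb_class", "stat")])
  for (m in seq_len(nrow(metrics))) {
    sel <- home$metric == metrics$metric[m] &
      (home$metric == "percentile" | home$wb_class %in% metrics$wb_class[m]) &
      home$stat == metrics$stat[m]
    w <- merge(home[sel & home$state == "ON", c("subject", "value")],
               home[sel & home$state == "not_ON", c("subject", "value")],
               by = "subject", suffixes = c("_on", "_noton"))
    cmp <- paired_compare(w$value_on, w$value_noton, alpha)
    varname <- if (metrics$metric[m] == "percentile")
      paste0("home_", metrics$stat[m]) else
        paste0("home_wb_", metrics$wb_class[m], "_", metrics$stat[m])
    rows[[length(rows) + 1L]] <- data.frame(
      domain = "home", variable = varname, n = cmp$n,
      test_used = cmp$test_used, p = cmp$p,
      flags = paste(cmp$flags, collapse = ","))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# UPDRS-III totals and gait item vs home percentiles, matching states
.clinical_correlations <- function(clinical, home, alpha) {
  specs <- list(
    list(score = "updrs3_on", state = "ON"),
    list(score = "item30_on", state = "ON"),
    list(score = "updrs3_off", state = "not_ON"),
    list(score = "item30_off", state = "not_ON"))
  rows <- list()
  for (sp in specs) {
    if (!sp$score %in% names(clinical)) next
    for (st in c("p25", "p50", "p75", "p90", "max")) {
      h <- home[home$state == sp$state & home$metric == "percentile" &
                  home$stat == st, c("subject", "value")]
      mg <- merge(data.frame(subject = clinical$subject_id,
                             score = clinical[[sp$score]]), h,
                  by = "subject")
      cr <- correlate_paired(mg$score, mg$value, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        score = sp$score, home_state = sp$state, stat = st, n = cr$n,
        corr_used = cr$corr_used, r = cr$r, corr_p = cr$corr_p,
        band = cr$band, flags = paste(cr$flags, collapse = ","))
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects, %d grid cells\n",
              x$n_subjects, if (is.null(x$grid)) 0L else nrow(x$grid)))
  invisible(x)
}
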