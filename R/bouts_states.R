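#' Classify walking-bout durations
#'
#' Free-living walking bouts are stratified by duration: bouts shorter
#' than 15 s are excluded from analysis, 15-30 s is `short`, more than 30
#' and up to 60 s is `medium`, and above 60 s is `long`. The 30 s tie
#' belongs to `short` (the medium class is open on the left).
#'
#' @param duration numeric vector of bout durations, s.
#' @return factor with levels `excluded_short`, `short`, `medium`, `long`.
#' @export
classify_bout_duration <- function(duration) {
  cls <- ifelse(duration < 15, "excluded_short",
         ifelse(duration <= 30, "short",
         ifelse(duration <= 60, "medium", "long")))
  factor(cls, levels = BOUT_CLASSES)
}

BOUT_CLASSES <- c("excluded_short", "short", "medium", "long")
WB_CLASSES <- c("short", "medium", "long")

#' Segment a stride sequence into walking bouts
#'
#' A walking bout is a maximal run of consecutive strides whose
#' inter-stride gap (next `t_start` minus current `t_end`) does not exceed
#' `max_gap`. Segmentation uses the full stride sequence; the slow-stride
#' speed filter only affects each bout's `mean_speed`, which is averaged
#' over strides at or above `min_speed`.
#'
#' @param strides stride data.frame (`t_start`, `t_end`, `speed`),
#'   time-ordered.
#' @param max_gap maximum within-bout inter-stride gap, s.
#' @param min_speed stride speed floor (m/s) for the bout mean.
#' @return data.frame of class `bout_table`: one row per bout with
#'   `bout`, `t_start`, `t_end`, `duration`, `length_class`, `n_strides`,
#'   `n_retained`, `mean_speed` (NA when no stride passes the speed
#'   filter).
#' @export
segment_bouts <- function(strides, max_gap = 3, min_speed = 0.2) {
  if (!nrow(strides)) {
    out <- data.frame(bout = integer(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      length_class = factor(character(0), levels = BOUT_CLASSES),
                      n_strides = integer(0), n_retained = integer(0),
                      mean_speed = numeric(0))
    class(out) <- c("bout_table", "data.frame")
    return(out)
  }
  if (is.unsorted(strides$t_start))
    stop("strides must be time-ordered")
  n <- nrow(strides)
  gap <- strides$t_start[-1L] - strides$t_end[-n]
  bout_id <- cumsum(c(1L, as.integer(gap > max_gap)))
  retained_speed <- ifelse(strides$speed >= min_speed, strides$speed, NA_real_)
  t_start <- tapply(strides$t_start, bout_id, min)
  t_end <- tapply(strides$t_end, bout_id, max)
  n_strides <- as.integer(tapply(strides$t_start, bout_id, length))
  n_retained <- as.integer(tapply(!is.na(retained_speed), bout_id, sum))
  mean_speed <- tapply(retained_speed, bout_id, mean, na.rm = TRUE)
  mean_speed[n_retained == 0L] <- NA_real_
  duration <- as.numeric(t_end - t_start)
  out <- data.frame(bout = as.integer(names(t_start)),
                    t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                    duration = duration,
                    length_class = classify_bout_duration(duration),
                    n_strides = n_strides, n_retained = n_retained,
                    mean_speed = as.numeric(mean_speed))
  rownames(out) <- NULL
  class(out) <- c("bout_table", "data.frame")
  out
}

#' Remove slow strides ahead of speed summaries
#'
#' Gait cycles below `min_speed` are treated as static periods and removed
#' from all speed summaries (bout segmentation itself runs on the
#' unfiltered sequence). The boundary is kept: the rule drops strides
#' strictly slower than the floor.
#'
#' @param strides stride data.frame with a `speed` column.
#' @param min_speed speed floor in m/s.
#' @return the retained strides; when nothing survives, an empty
#'   data.frame with attribute `flag = "all_strides_below_speed_floor"`.
#' @export
filter_strides <- function(strides, min_speed = 0.2) {
  keep <- strides$speed >= min_speed
  out <- strides[keep, , drop = FALSE]
  if (!nrow(out) && nrow(strides))
    attr(out, "flag") <- "all_strides_below_speed_floor"
  out
}

#' Build a medication-state timeline from intake events
#'
#' Each dopaminergic intake at time `t` defines an ON window 60-180 min
#' after intake and a not-ON window from 30 min before to 30 min after
#' intake. Windows from all intakes are unioned per state; where an ON
#' window from one dose collides with a not-ON window from another
#' (possible when doses are closer than 210 min), `overlap_policy`
#' resolves the conflict. All remaining time is unlabeled.
#'
#' @param intakes numeric vector of intake times (s), or a data.frame with
#'   a `time` column (as from [read_diary()]).
#' @param on_window ON window relative to intake, s (default 3600-10800).
#' @param noton_window not-ON window relative to intake, s (default
#'   -1800 to 1800).
#' @param overlap_policy `"noton_wins"` (default: proximity to an intake
#'   means the drug effect is not yet established), `"on_wins"`, or
#'   `"drop"` (contested time becomes unlabeled).
#' @return data.frame of class `state_timeline`: `start`, `end`, `state`
#'   (`"ON"` / `"not_ON"`), sorted and disjoint.
#' @export
build_state_timeline <- function(intakes, on_window = c(3600, 10800),
                                 noton_window = c(-1800, 1800),
                                 overlap_policy = c("noton_wins", "on_wins",
                                                    "drop")) {
  overlap_policy <- match.arg(overlap_policy)
  if (is.data.frame(intakes)) intakes <- intakes$time
  intakes <- sort(unique(as.numeric(intakes)))
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      state = character(0))
  if (!length(intakes)) {
    class(empty) <- c("state_timeline", "data.frame")
    return(empty)
  }
  on_raw <- iv_union(cbind(intakes + on_window[1L], intakes + on_window[2L]))
  noton_raw <- iv_union(cbind(intakes + noton_window[1L],
                              intakes + noton_window[2L]))
  resolved <- switch(overlap_policy,
    noton_wins = list(on = iv_diff(on_raw, noton_raw), noton = noton_raw),
    on_wins = list(on = on_raw, noton = iv_diff(noton_raw, on_raw)),
    drop = list(on = iv_diff(on_raw, noton_raw),
                noton = iv_diff(noton_raw, on_raw)))
  tl <- rbind(
    if (nrow(resolved$on))
      data.frame(start = resolved$on[, 1], end = resolved$on[, 2],
                 state = "ON"),
    if (nrow(resolved$noton))
      data.frame(start = resolved$noton[, 1], end = resolved$noton[, 2],
                 state = "not_ON"))
  if (is.null(tl)) tl <- empty
  tl <- tl[order(tl$start), , drop = FALSE]
  rownames(tl) <- NULL
  class(tl) <- c("state_timeline", "data.frame")
  tl
}

# union of closed intervals given as a 2-column matrix; rows may overlap
iv_union <- function(m) {
  if (!nrow(m)) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) out[j, 2] <- max(out[j, 2], m[i, 2])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

# set difference a \ b for disjoint sorted interval matrices
iv_diff <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  pieces <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    cur_s <- s
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1]; be <- b[j, 2]
      if (be <= cur_s || bs >= e) next
      if (bs > cur_s) pieces <- rbind(pieces, c(cur_s, bs))
      cur_s <- max(cur_s, be)
      if (cur_s >= e) break
    }
    if (cur_s < e) pieces <- rbind(pieces, c(cur_s, e))
  }
  pieces
}

#' Look up the medication state at given times
#'
#' Intervals are treated as closed on the left and open on the right, so a
#' time exactly at an ON window's start is ON.
#'
#' @param times numeric vector, s.
#' @param timeline a `state_timeline`.
#' @return character vector `"ON"` / `"not_ON"` / `"unlabeled"`.
#' @export
state_at <- function(times, timeline) {
  out <- rep("unlabeled", length(times))
  for (i in seq_len(nrow(timeline))) {
    hit <- times >= timeline$start[i] & times < timeline$end[i]
    out[hit] <- timeline$state[i]
  }
  out
}

#' Assign medication states to bouts or strides
#'
#' The state of a bout (or stride) is the timeline label at its midpoint;
#' rows whose midpoint falls in unlabeled time get `"unlabeled"`. The rule
#' is a pure function of (midpoint, timeline), so it is invariant to row
#' order and applies identically at stride level for the percentile
#' approach.
#'
#' @param x data.frame with `t_start` and `t_end` columns (bout or stride
#'   table).
#' @param timeline a `state_timeline` from [build_state_timeline()].
#' @return `x` with a `state` column added.
#' @export
assign_states <- function(x, timeline) {
  x$state <- state_at((x$t_start + x$t_end) / 2, timeline)
  x
}
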