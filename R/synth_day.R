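#' Scenario for one simulated 12-hour patient day
#'
#' Defines the stochastic model of a free-living day: the dosing
#' schedule, a Poisson walking-bout process whose rate may differ by
#' medication state, log-normal bout durations, and a state-dependent
#' stride-speed model built on a latent subject capacity.
#'
#' The speed model: a subject has gait capacity `c` (m/s scale, roughly
#' the supervised normal-pace speed) and a medication response `d < 1`
#' multiplying speeds when the drug effect is absent. Ordinary
#' ("habitual") bouts run at `k_on * c * exp(eta)` (ON) or
#' `k_off * c * d * exp(eta)` (not-ON), where `exp(eta)` is a
#' subject-level behavioral factor: how fast a person chooses to walk at
#' home is not fully determined by capacity. Two special bout types tie
#' the distribution tails to capacity: during ON, a fraction `p_brisk` of
#' bouts are purposeful brisk walks near `brisk_level * c` (they form the
#' upper tail), and during not-ON a fraction `p_slow` of bouts sit at the
#' impairment floor `slow_level * c * d` (they form the lower tail). This
#' is the mechanism behind the supervised-vs-unsupervised signature the
#' pipeline is designed to detect: ON capacity shows up in the fast tail
#' of home walking, OFF impairment in the slow tail.
#'
#' @param duration day length, s (12 h).
#' @param intake_times dopaminergic intake times, s from day start
#'   (default three doses at 0.5 h, 4.5 h and 8.5 h, i.e. 09:30, 13:30
#'   and 17:30 for a 9 a.m. start).
#' @param bout_rate named bouts/hour for `on`, `noton`, `unlabeled` time.
#' @param bout_duration log-normal duration parameters
#'   (`meanlog`, `sdlog`), s.
#' @param capacity_mean,capacity_sd latent capacity distribution, m/s.
#' @param resp_mean,resp_sd medication-response multiplier distribution.
#' @param behav_sd SD of the subject-level behavioral log-factor `eta`.
#' @param k_on,k_off habitual speed multipliers by state.
#' @param sigma_w within-bout stride-speed SD, m/s.
#' @param p_brisk,brisk_level,p_slow,slow_level tail-bout parameters (see
#'   above).
#' @param sigma_tail stride-speed SD inside tail bouts, m/s.
#' @param stride_time_mean,stride_time_sd gait-cycle duration model, s.
#' @return list of class `day_scenario`.
#' @export
day_scenario <- function(duration = 12 * 3600,
                         intake_times = c(1800, 16200, 30600),
                         bout_rate = c(on = 7, noton = 7, unlabeled = 7),
                         bout_duration = list(meanlog = log(20), sdlog = 0.8),
                         capacity_mean = 1.0, capacity_sd = 0.15,
                         resp_mean = 0.93, resp_sd = 0.04,
                         behav_sd = 0.15,
                         k_on = 0.83, k_off = 0.77,
                         sigma_w = 0.12,
                         p_brisk = 0.15, brisk_level = 1.45,
                         p_slow = 0.30, slow_level = 0.55,
                         sigma_tail = 0.06,
                         stride_time_mean = 1.1, stride_time_sd = 0.08) {
  structure(as.list(environment()), class = "day_scenario")
}

# contiguous labeled regions covering [0, duration]
timeline_regions <- function(timeline, duration) {
  edges <- sort(unique(c(0, duration,
                         pmax(0, pmin(duration, timeline$start)),
                         pmax(0, pmin(duration, timeline$end)))))
  starts <- edges[-length(edges)]
  ends <- edges[-1L]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(start = starts, end = ends,
             state = state_at((starts + ends) / 2, timeline))
}

# draw one subject's latent parameters
draw_subject <- function(sc) {
  list(capacity = stats::rnorm(1, sc$capacity_mean, sc$capacity_sd),
       resp = pmin(1, stats::rnorm(1, sc$resp_mean, sc$resp_sd)),
       eta = stats::rnorm(1, 0, sc$behav_sd))
}

# mean stride speed of one bout given its type and the subject
bout_speed_mean <- function(sc, subj, state, type) {
  switch(type,
    brisk = sc$brisk_level * subj$capacity,
    slow = sc$slow_level * subj$capacity * subj$resp,
    habitual = if (state == "ON")
      sc$k_on * subj$capacity * exp(subj$eta)
    else sc$k_off * subj$capacity * subj$resp * exp(subj$eta))
}

#' Simulate one free-living patient day
#'
#' Generates the day's medication-state timeline from the intake
#' schedule, draws walking bouts from a Poisson process within each
#' state region, tiles strides inside each bout, and draws state- and
#' type-dependent stride speeds (see [day_scenario()]). Unlabeled time
#' uses the ON habitual speed model. Every stride carries its true state
#' and true speed. Optionally, the full IMU signal is synthesized with
#' [synth_walk()] for end-to-end runs at reduced duration.
#'
#' @param scenario a [day_scenario()].
#' @param subject optional list (`capacity`, `resp`, `eta`); drawn from
#'   the scenario when NULL.
#' @param seed optional RNG seed: the whole day is reproducible given a
#'   seed and scenario.
#' @param signals also synthesize the raw IMU recording (slow; meant for
#'   short scenarios).
#' @param tile_strides fill bouts with strides (disable to study the bout
#'   process alone).
#' @return list: `strides` (truth table: `t_start`, `t_end`, `duration`,
#'   `speed`, `state_true`, `bout`, `bout_type`), `bouts_true` (the bout
#'   process ground truth, including each bout's `duration_drawn` before
#'   truncation at region ends or the next bout), `diary` (data.frame
#'   `time`, `dose_label`), `timeline`, `subject`, and `rec` (an
#'   [imu_recording()], only when `signals = TRUE`).
#' @export
synth_day <- function(scenario = day_scenario(), subject = NULL,
                      seed = NULL, signals = FALSE, tile_strides = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  if (is.null(subject)) subject <- draw_subject(sc)
  timeline <- build_state_timeline(sc$intake_times)
  regions <- timeline_regions(timeline, sc$duration)
  bouts <- list()
  for (i in seq_len(nrow(regions))) {
    len <- regions$end[i] - regions$start[i]
    state <- regions$state[i]
    rate_key <- switch(state, ON = "on", not_ON = "noton", "unlabeled")
    nb <- stats::rpois(1, sc$bout_rate[[rate_key]] * len / 3600)
    if (!nb) next
    starts <- sort(stats::runif(nb, regions$start[i], regions$end[i]))
    durs <- stats::rlnorm(nb, sc$bout_duration$meanlog,
                          sc$bout_duration$sdlog)
    ends <- pmin(starts + durs, regions$end[i],
                 c(starts[-1L], Inf))  # truncate at the next bout start
    keep <- ends - starts >= 2
    if (!any(keep)) next
    bouts[[length(bouts) + 1L]] <- data.frame(
      t_start = starts[keep], t_end = ends[keep], state = state,
      duration_drawn = durs[keep])
  }
  diary <- data.frame(
    time = sc$intake_times,
    dose_label = sprintf("dose_%d", seq_along(sc$intake_times)))
  bouts_true <- NULL
  if (!tile_strides && length(bouts)) {
    bouts_true <- do.call(rbind, bouts)
    return(list(strides = NULL, bouts_true = bouts_true, diary = diary,
                timeline = timeline, subject = subject))
  }
  if (!length(bouts)) {
    strides <- data.frame(t_start = numeric(0), t_end = numeric(0),
                          duration = numeric(0), speed = numeric(0),
                          state_true = character(0), bout = integer(0),
                          bout_type = character(0))
  } else {
    bouts <- do.call(rbind, bouts)
    bouts_true <- bouts
    nb <- nrow(bouts)
    t_start <- t_end <- duration <- speed <- numeric(0)
    state_true <- bout_type <- character(0)
    bout_id <- integer(0)
    for (b in seq_len(nb)) {
      state <- bouts$state[b]
      eff_state <- if (state == "not_ON") "not_ON" else "ON"
      u <- stats::runif(1)
      type <- if (eff_state == "ON" && u < sc$p_brisk) "brisk"
      else if (eff_state == "not_ON" && u < sc$p_slow) "slow"
      else "habitual"
      mu <- bout_speed_mean(sc, subject, eff_state, type)
      sig <- if (type == "habitual") sc$sigma_w else sc$sigma_tail
      dur <- bouts$t_end[b] - bouts$t_start[b]
      n_max <- ceiling(dur / 0.8) + 1L
      st <- pmin(pmax(stats::rnorm(n_max, sc$stride_time_mean,
                                   sc$stride_time_sd), 0.8), 1.6)
      ends <- cumsum(st)
      st <- st[ends <= dur]
      ns <- length(st)
      if (!ns) next
      t0 <- bouts$t_start[b] + cumsum(c(0, st[-ns]))
      t_start <- c(t_start, t0)
      t_end <- c(t_end, t0 + st)
      duration <- c(duration, st)
      speed <- c(speed, pmax(0.05, stats::rnorm(ns, mu, sig)))
      state_true <- c(state_true, rep(state, ns))
      bout_type <- c(bout_type, rep(type, ns))
      bout_id <- c(bout_id, rep(b, ns))
    }
    strides <- data.frame(t_start = t_start, t_end = t_end,
                          duration = duration, speed = speed,
                          state_true = state_true, bout = bout_id,
                          bout_type = bout_type)
  }
  out <- list(strides = strides, bouts_true = bouts_true, diary = diary,
              timeline = timeline, subject = subject)
  if (signals && nrow(strides)) {
    fs <- 128
    specs <- lapply(seq_len(nrow(strides)), function(i)
      stride_spec(stride_length = strides$speed[i] * strides$duration[i],
                  duration = strides$duration[i], fs = fs))
    gaps <- c(strides$t_start[-1L] - strides$t_end[-nrow(strides)], 0)
    out$rec <- synth_walk(specs, rest_gaps = pmax(0, gaps))$rec
  }
  out
}

#' Scenario for a synthetic cohort
#'
#' Links supervised and free-living speeds through each subject's shared
#' latent capacity: lab task means are `fast = 1.25 c`,
#' `normal = 1.0 c`, `circular = 0.7 c` (times the medication response
#' `d` in the OFF state) plus trial noise, while the home day is
#' generated by [synth_day()] from the same `c`, `d` and behavioral
#' factor. Per-subject ground-truth parameters are stored alongside the
#' outputs.
#'
#' @param n_subjects cohort size.
#' @param day a [day_scenario()] shared by all subjects.
#' @param task_mult named lab-task multipliers of capacity.
#' @param lab_noise_sd SD of lab trial means around their target, m/s.
#' @param circular_noise_sd extra noise on the circular task, m/s.
#' @param n_fast_off how many subjects manage the fast task in OFF.
#' @return list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_subjects = 27, day = day_scenario(),
                            task_mult = c(straight_normal = 1.0,
                                          straight_fast = 1.25,
                                          circular = 0.7),
                            lab_noise_sd = 0.03, circular_noise_sd = 0.04,
                            n_fast_off = 2) {
  structure(list(n_subjects = n_subjects, day = day,
                 task_mult = task_mult, lab_noise_sd = lab_noise_sd,
                 circular_noise_sd = circular_noise_sd,
                 n_fast_off = n_fast_off),
            class = "cohort_scenario")
}

#' Simulate a full cohort: lab trials, home days, diaries, truth
#'
#' @param scenario a [cohort_scenario()].
#' @param seed RNG seed; the full dataset is reproducible given the seed.
#' @return list of class `synth_cohort`: `lab` (data.frame `subject`,
#'   `task`, `med_state`, `mean_speed`), `home` (per-subject list with
#'   `strides`, `diary`, `timeline`), `truth` (per-subject latent
#'   parameters), `scenario`.
#' @export
synth_cohort <- function(scenario = cohort_scenario(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  subjects <- sprintf("S%02d", seq_len(sc$n_subjects))
  truth <- list(); lab <- list(); home <- list()
  fast_off_ids <- subjects[seq_len(min(sc$n_fast_off, sc$n_subjects))]
  for (i in seq_len(sc$n_subjects)) {
    subj <- draw_subject(sc$day)
    truth[[i]] <- data.frame(subject = subjects[i],
                             capacity = subj$capacity, resp = subj$resp,
                             eta = subj$eta)
    for (task in names(sc$task_mult)) for (state in c("ON", "OFF")) {
      if (task == "straight_fast" && state == "OFF" &&
          !(subjects[i] %in% fast_off_ids)) next
      mult <- sc$task_mult[[task]]
      target <- mult * subj$capacity * (if (state == "OFF") subj$resp else 1)
      noise_sd <- sc$lab_noise_sd +
        (if (task == "circular") sc$circular_noise_sd else 0)
      lab[[length(lab) + 1L]] <- data.frame(
        subject = subjects[i], task = task, med_state = state,
        mean_speed = max(0.1, target + stats::rnorm(1, 0, noise_sd)))
    }
    home[[i]] <- synth_day(sc$day, subject = subj)
  }
  names(home) <- subjects
  structure(list(lab = do.call(rbind, lab), home = home,
                 truth = do.call(rbind, truth), scenario = sc),
            class = "synth_cohort")
}

#' Run the home-side pipeline on a synthetic cohort
#'
#' For each subject: segment bouts, assign medication states from the
#' diary-derived timeline, and summarize both states. Returns the long
#' home-summary table ready for [build_cohort_grid()].
#'
#' @param cohort a [synth_cohort()].
#' @param max_gap,min_speed bout segmentation / speed-filter settings.
#' @return data.frame as from [home_summary_table()].
#' @export
cohort_home_summaries <- function(cohort, max_gap = 3, min_speed = 0.2) {
  summaries <- list()
  for (id in names(cohort$home)) {
    day <- cohort$home[[id]]
    timeline <- build_state_timeline(day$diary)
    strides <- assign_states(day$strides, timeline)
    bouts <- assign_states(segment_bouts(strides, max_gap, min_speed),
                           timeline)
    for (state in c("ON", "not_ON"))
      summaries[[length(summaries) + 1L]] <-
        summarize_subject(strides, bouts, state, min_speed, subject_id = id)
  }
  home_summary_table(summaries)
}
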