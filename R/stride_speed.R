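#' Detect still (foot-flat) periods in a foot-IMU recording
#'
#' A sample is judged motionless when the gyroscope magnitude is below
#' `gyro_thresh` and the accelerometer magnitude is within `accel_band` of
#' gravity. Gaps of up to 2 samples inside still runs are closed
#' (morphological closing) and runs shorter than `min_still` are
#' discarded. The resulting still intervals anchor the zero-velocity
#' updates of [estimate_strides()].
#'
#' @param rec an [imu_recording()] in internal units.
#' @param gyro_thresh gyroscope magnitude threshold, rad/s.
#' @param accel_band half-width of the allowed band around gravity, m/s^2.
#' @param min_still minimum still duration, s.
#' @return object of class `zupt_mask`: list with `mask` (logical per
#'   sample), `intervals` (data.frame `start`, `end` sample indices,
#'   `t_start`, `t_end` seconds), and `fs`.
#' @export
detect_still <- function(rec, gyro_thresh = 0.8, accel_band = 0.8,
                         min_still = 0.08) {
  gmag <- sqrt(rowSums(rec$gyro^2))
  amag <- sqrt(rowSums(rec$accel^2))
  mask <- gmag < gyro_thresh & abs(amag - GRAVITY_MS2) < accel_band

  # close FALSE gaps of <= 2 samples flanked by TRUE runs
  mask2 <- mask
  runs <- rle(mask)
  if (length(runs$lengths) >= 3L) {
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (i in seq_along(runs$lengths)) {
      if (!runs$values[i] && runs$lengths[i] <= 2L &&
          i > 1L && i < length(runs$lengths))
        mask2[idx_start[i]:idx_end[i]] <- TRUE
    }
  }
  # drop TRUE runs shorter than min_still
  min_n <- max(2L, ceiling(min_still * rec$fs))
  runs <- rle(mask2)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i] && runs$lengths[i] < min_n)
      mask2[idx_start[i]:idx_end[i]] <- FALSE
  }
  runs <- rle(mask2)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  keep <- which(runs$values)
  intervals <- data.frame(
    start = idx_start[keep], end = idx_end[keep],
    t_start = rec$time[idx_start[keep]], t_end = rec$time[idx_end[keep]])
  structure(list(mask = mask2, intervals = intervals, fs = rec$fs),
            class = "zupt_mask")
}

#' @export
print.zupt_mask <- function(x, ...) {
  cat(sprintf("<zupt_mask> %d/%d samples still, %d still interval(s)\n",
              sum(x$mask), length(x$mask), nrow(x$intervals)))
  invisible(x)
}

#' Default settings for the stride-speed estimator
#'
#' @param gyro_thresh,accel_band,min_still still-detection thresholds,
#'   see [detect_still()].
#' @param max_stride_duration movement intervals longer than this (s) are
#'   not integrated: they are flagged and no stride is emitted.
#' @param max_flat cap (s) on how much of a long preceding still interval
#'   counts as the foot-flat phase of the next gait cycle; a stride whose
#'   preceding still exceeds it is flagged `after_rest`.
#' @param max_speed sanity bound (m/s); faster strides are flagged
#'   `overspeed`.
#' @return named list of settings.
#' @export
stride_params <- function(gyro_thresh = 0.8, accel_band = 0.8,
                          min_still = 0.08, max_stride_duration = 4,
                          max_flat = 0.8, max_speed = 4) {
  list(gyro_thresh = gyro_thresh, accel_band = accel_band,
       min_still = min_still, max_stride_duration = max_stride_duration,
       max_flat = max_flat, max_speed = max_speed)
}

#' Estimate per-stride gait speed by ZUPT strapdown integration
#'
#' For every movement interval between two consecutive still intervals:
#' orientation is initialized from the gravity direction measured over the
#' preceding still period, the gyroscope is strapdown-integrated
#' (quaternion, trapezoidal increments) to track orientation, the
#' accelerometer is rotated to the navigation frame and gravity is
#' subtracted, acceleration is integrated to velocity, the zero-velocity
#' constraint at both bounding still intervals is enforced by removing the
#' linear drift ramp, and velocity is integrated to displacement. One
#' stride per interval is emitted with
#' `speed = ||displacement|| / duration`, where duration runs from
#' foot-flat onset to the next foot-flat onset (one gait cycle).
#'
#' @param rec an [imu_recording()].
#' @param mask a `zupt_mask` from [detect_still()]; computed with the
#'   settings in `params` when omitted.
#' @param params settings list from [stride_params()].
#' @return data.frame of class `stride_table` with one row per stride:
#'   `t_start`, `t_end`, `duration`, `displacement` (m, 3-D norm), `speed`
#'   (m/s) and `flags` (comma-separated quality flags, `""` when clean).
#' @export
estimate_strides <- function(rec, mask = NULL, params = stride_params()) {
  if (is.null(mask))
    mask <- detect_still(rec, params$gyro_thresh, params$accel_band,
                         params$min_still)
  iv <- mask$intervals
  if (nrow(iv) < 2L) return(empty_stride_table())
  out <- vector("list", nrow(iv) - 1L)
  for (i in seq_len(nrow(iv) - 1L)) {
    k0 <- iv$end[i]          # last sample of preceding still
    k1 <- iv$start[i + 1L]   # first sample of following still
    move_dur <- rec$time[k1] - rec$time[k0]
    if (move_dur > params$max_stride_duration) next
    seg <- integrate_interval(rec, iv, i, k0, k1)
    flags <- character(0)
    t_start <- iv$t_start[i]
    if (rec$time[k0] - iv$t_start[i] > params$max_flat) {
      t_start <- rec$time[k0] - params$max_flat
      flags <- c(flags, "after_rest")
    }
    t_end <- iv$t_start[i + 1L]
    duration <- t_end - t_start
    speed <- seg$displacement / duration
    if (speed >= params$max_speed) flags <- c(flags, "overspeed")
    out[[i]] <- data.frame(
      t_start = t_start, t_end = t_end, duration = duration,
      displacement = seg$displacement, speed = speed,
      flags = paste(flags, collapse = ","))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_stride_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("stride_table", "data.frame")
  res
}

empty_stride_table <- function() {
  res <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    duration = numeric(0), displacement = numeric(0),
                    speed = numeric(0), flags = character(0))
  class(res) <- c("stride_table", "data.frame")
  res
}

# Strapdown integration of one movement interval [k0, k1].
# Returns the 3-D displacement norm; the linear drift ramp is removed so
# that velocity is exactly zero at both bounding still samples.
integrate_interval <- function(rec, iv, i, k0, k1) {
  # gravity direction from the tail of the preceding still interval
  a0 <- iv$start[i]
  tail_start <- max(a0, k0 - as.integer(ceiling(0.5 * rec$fs)))
  f_mean <- colMeans(rec$accel[tail_start:k0, , drop = FALSE])
  q <- quat_between(f_mean, c(0, 0, 1))

  idx <- k0:k1
  n <- length(idx)
  tt <- rec$time[idx]
  a_nav <- matrix(0, n, 3)
  f0 <- rec$accel[idx[1L], ]
  a_nav[1L, ] <- quat_to_matrix(q) %*% f0 - c(0, 0, GRAVITY_MS2)
  for (j in seq_len(n - 1L)) {
    dt <- tt[j + 1L] - tt[j]
    rv <- (rec$gyro[idx[j], ] + rec$gyro[idx[j + 1L], ]) / 2 * dt
    q <- quat_mul(q, quat_from_rotvec(rv))
    a_nav[j + 1L, ] <- quat_to_matrix(q) %*% rec$accel[idx[j + 1L], ] -
      c(0, 0, GRAVITY_MS2)
  }
  v <- apply(a_nav, 2L, cumtrapz_vec, tt = tt)
  # zero-velocity update: subtract the linear ramp through the endpoints
  ramp <- (tt - tt[1L]) / (tt[n] - tt[1L])
  v <- v - outer(ramp, v[n, ])
  disp <- vapply(1:3, function(c3) trapz_vec(tt, v[, c3]), numeric(1))
  list(displacement = sqrt(sum(disp^2)), v_end = sqrt(sum(v[n, ]^2)))
}

cumtrapz_vec <- function(y, tt) {
  n <- length(y)
  c(0, cumsum((y[-1L] + y[-n]) / 2 * diff(tt)))
}

trapz_vec <- function(tt, y) {
  n <- length(y)
  sum((y[-1L] + y[-n]) / 2 * diff(tt))
}

#' Construct a laboratory gait trial
#'
#' @param recording an [imu_recording()].
#' @param task one of `"straight_normal"`, `"straight_fast"`,
#'   `"circular_left"`, `"circular_right"`.
#' @param med_state `"ON"` or `"OFF"`.
#' @return object of class `lab_trial`. A fast-pace trial in the OFF state
#'   is allowed but flagged (few fluctuating patients manage it).
#' @export
lab_trial <- function(recording, task = c("straight_normal", "straight_fast",
                                          "circular_left", "circular_right"),
                      med_state = c("ON", "OFF")) {
  task <- match.arg(task)
  med_state <- match.arg(med_state)
  flags <- character(0)
  if (task == "straight_fast" && med_state == "OFF")
    flags <- "fast_pace_off_state"
  structure(list(recording = recording, task = task, med_state = med_state,
                 flags = flags), class = "lab_trial")
}

#' Steady-state mean gait speed of a lab trial
#'
#' Runs still detection and stride estimation on the trial recording, then
#' drops the first two and last two gait cycles (acceleration and
#' deceleration phases) and averages the remaining speeds.
#'
#' @param trial a [lab_trial()].
#' @param params settings from [stride_params()].
#' @return list of class `trial_speed_result`: `strides` (all detected),
#'   `retained` (after trimming), `mean_speed` (NA when nothing remains),
#'   `n_trimmed`, `flags`.
#' @export
process_lab_trial <- function(trial, params = stride_params()) {
  stopifnot(inherits(trial, "lab_trial"))
  strides <- estimate_strides(trial$recording, params = params)
  n <- nrow(strides)
  n_trimmed <- min(4L, n)
  retained <- if (n > 4L) strides[3:(n - 2L), , drop = FALSE] else
    strides[0L, , drop = FALSE]
  flags <- trial$flags
  if (n < 5L) flags <- c(flags, "insufficient_steady_state_strides")
  mean_speed <- if (nrow(retained)) mean(retained$speed) else NA_real_
  structure(list(task = trial$task, med_state = trial$med_state,
                 strides = strides, retained = retained,
                 mean_speed = mean_speed, n_trimmed = n_trimmed,
                 flags = flags),
            class = "trial_speed_result")
}

#' @export
print.trial_speed_result <- function(x, ...) {
  cat(sprintf("<trial_speed_result> %s/%s: %d strides, %d trimmed, mean %.3f m/s%s\n",
              x$task, x$med_state, nrow(x$strides), x$n_trimmed,
              x$mean_speed,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
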