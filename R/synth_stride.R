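#' Specify one synthetic stride's kinematics
#'
#' A synthetic gait cycle is a foot-flat phase followed by a swing phase.
#' The swing follows a closed-form trajectory: forward progression with a
#' raised-cosine speed bump (zero velocity at both ends), a sinusoidal
#' foot-clearance arc, a smooth pitch excursion, and (for curved walking)
#' a smooth heading change. Because every channel is analytic, the true
#' displacement and speed are known exactly.
#'
#' @param stride_length path length of the swing, m.
#' @param duration full gait-cycle duration (foot-flat onset to next
#'   foot-flat onset), s.
#' @param swing_fraction fraction of the cycle spent moving (0-1).
#' @param clearance peak foot lift, m.
#' @param pitch_amp peak pitch excursion during swing, rad.
#' @param turn_angle heading change over the stride, rad (0 = straight).
#' @param noise list: `accel_sigma` (m/s^2), `gyro_sigma` (rad/s),
#'   `gyro_bias` (rad/s, constant-magnitude bias vector).
#' @param fs sampling rate, Hz.
#' @return list of class `stride_spec`.
#' @export
stride_spec <- function(stride_length = 1.3, duration = 1.1,
                        swing_fraction = 0.65, clearance = 0.08,
                        pitch_amp = 0.5, turn_angle = 0,
                        noise = list(accel_sigma = 0.05, gyro_sigma = 0.01,
                                     gyro_bias = 0.005),
                        fs = 128) {
  stopifnot(stride_length >= 0, duration > 0,
            swing_fraction > 0, swing_fraction < 1, fs > 0)
  if (duration * fs < 20)
    stop("stride too short: duration * fs must be at least 20 samples")
  structure(list(stride_length = stride_length, duration = duration,
                 swing_fraction = swing_fraction, clearance = clearance,
                 pitch_amp = pitch_amp, turn_angle = turn_angle,
                 noise = noise, fs = fs),
            class = "stride_spec")
}

NOISELESS <- list(accel_sigma = 0, gyro_sigma = 0, gyro_bias = 0)

# Ideal (noise-free) body-frame signals of one stride, evaluated at times
# tau in [0, duration) relative to the stride start. heading0 is the yaw
# at stride start. Returns accel (specific force, m/s^2) and gyro (rad/s),
# n x 3 each.
stride_signal_at <- function(spec, tau, heading0 = 0) {
  n <- length(tau)
  Tf <- (1 - spec$swing_fraction) * spec$duration
  Tm <- spec$swing_fraction * spec$duration
  L <- spec$stride_length; h <- spec$clearance
  A <- spec$pitch_amp; dpsi <- spec$turn_angle
  u <- (tau - Tf) / Tm
  moving <- u >= 0 & u < 1
  accel <- matrix(rep(c(0, 0, GRAVITY_MS2), each = n), n, 3)
  gyro <- matrix(0, n, 3)
  if (any(moving)) {
    um <- u[moving]
    s2 <- sin(2 * pi * um); c2 <- cos(2 * pi * um)
    v <- (L / Tm) * (1 - c2)                    # path speed
    vdot <- (2 * pi * L / Tm^2) * s2
    phi <- heading0 + dpsi * (um - s2 / (2 * pi))
    phidot <- (dpsi / Tm) * (1 - c2)
    az <- (2 * pi^2 * h / Tm^2) * c2
    theta <- A * s2 * sin(pi * um)^2
    thetadot <- A * (2 * pi * c2 * sin(pi * um)^2 + pi * s2^2) / Tm
    ax <- vdot * cos(phi) - v * phidot * sin(phi)
    ay <- vdot * sin(phi) + v * phidot * cos(phi)
    # specific force in navigation frame, then body frame via
    # R = Rz(phi) Ry(theta):  f_b = Ry(theta)^T Rz(phi)^T (a - g)
    fzn <- az + GRAVITY_MS2
    f1 <- cos(phi) * ax + sin(phi) * ay        # Rz^T
    f2 <- -sin(phi) * ax + cos(phi) * ay
    fb1 <- cos(theta) * f1 - sin(theta) * fzn  # Ry^T
    fb3 <- sin(theta) * f1 + cos(theta) * fzn
    accel[moving, 1] <- fb1
    accel[moving, 2] <- f2
    accel[moving, 3] <- fb3
    # body rates for R = Rz(phi) Ry(theta)
    gyro[moving, 1] <- -sin(theta) * phidot
    gyro[moving, 2] <- thetadot
    gyro[moving, 3] <- cos(theta) * phidot
  }
  list(accel = accel, gyro = gyro)
}

# True 3-D displacement of one stride. Straight strides are closed-form
# (the heading is constant, so the chord equals the path length); curved
# strides integrate the analytic velocity on a fine grid (51x the sample
# rate; quadrature error ~1e-9 m).
stride_truth_displacement <- function(spec, heading0 = 0) {
  L <- spec$stride_length
  if (spec$turn_angle == 0) return(L)
  Tm <- spec$swing_fraction * spec$duration
  m <- max(2001L, 51L * ceiling(Tm * spec$fs))
  um <- seq(0, 1, length.out = m)
  s2 <- sin(2 * pi * um)
  v <- (L / Tm) * (1 - cos(2 * pi * um))
  phi <- heading0 + spec$turn_angle * (um - s2 / (2 * pi))
  dx <- trapz_vec(um * Tm, v * cos(phi))
  dy <- trapz_vec(um * Tm, v * sin(phi))
  sqrt(dx^2 + dy^2)
}

#' Synthesize one stride's IMU segment with ground truth
#'
#' Emits the ideal accelerometer/gyroscope signals of a single gait cycle
#' (foot-flat, then swing) on the sample grid, adds the specified sensor
#' noise, and returns the analytically known stride record. The truth
#' speed is `||displacement|| / duration`; for straight strides the
#' displacement equals `stride_length` exactly.
#'
#' @param spec a [stride_spec()].
#' @param heading0 initial heading, rad.
#' @param seed optional RNG seed for the noise realization.
#' @return list: `time`, `accel`, `gyro` (segment channels), `truth`
#'   (one-row stride data.frame with the true displacement and speed).
#' @export
synth_stride_signal <- function(spec, heading0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- floor(spec$duration * spec$fs)
  tau <- (seq_len(n) - 1L) / spec$fs
  sig <- stride_signal_at(spec, tau, heading0)
  sig <- add_sensor_noise(sig, spec$noise)
  disp <- stride_truth_displacement(spec, heading0)
  truth <- data.frame(t_start = 0, t_end = spec$duration,
                      duration = spec$duration, displacement = disp,
                      speed = disp / spec$duration)
  list(time = tau, accel = sig$accel, gyro = sig$gyro, truth = truth)
}

add_sensor_noise <- function(sig, noise) {
  n <- nrow(sig$accel)
  if (noise$accel_sigma > 0)
    sig$accel <- sig$accel + matrix(stats::rnorm(3 * n, 0, noise$accel_sigma), n, 3)
  if (noise$gyro_bias > 0) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    sig$gyro <- sig$gyro + matrix(rep(dir * noise$gyro_bias, each = n), n, 3)
  }
  if (noise$gyro_sigma > 0)
    sig$gyro <- sig$gyro + matrix(stats::rnorm(3 * n, 0, noise$gyro_sigma), n, 3)
  sig
}

#' Synthesize a walk: a sequence of strides with optional rests
#'
#' Concatenates stride segments on a continuous time base, inserting
#' still (gravity-only) gaps where requested and a trailing still segment
#' so the final swing is bounded by a zero-velocity anchor. Heading
#' accumulates across strides (`turn_angle` per stride), so circular
#' walking is just a walk of turning strides. Sensor noise (taken from
#' the first spec) is applied once to the assembled recording, with a
#' single constant gyro-bias vector.
#'
#' @param specs a [stride_spec()] or list of them, one per stride.
#' @param rest_gaps still time inserted after each stride, s: scalar or
#'   vector of length `length(specs)` (last entry extends the tail).
#' @param final_still trailing still duration, s.
#' @param heading0 initial heading, rad.
#' @param seed optional RNG seed for the noise realization.
#' @param subject_id,device_context recording metadata.
#' @return list: `rec` (an [imu_recording()]) and `truth` (stride
#'   data.frame with true `t_start`, `t_end`, `duration`, `displacement`,
#'   `speed`).
#' @export
synth_walk <- function(specs, rest_gaps = 0, final_still = 0.4,
                       heading0 = 0, seed = NULL, subject_id = "synthetic",
                       device_context = "home") {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(specs, "stride_spec")) specs <- list(specs)
  ns <- length(specs)
  stopifnot(ns >= 1L)
  rest_gaps <- rep_len(rest_gaps, ns)
  fs <- specs[[1L]]$fs
  durs <- vapply(specs, `[[`, numeric(1), "duration")
  starts <- cumsum(c(0, (durs + rest_gaps)[-ns]))
  total <- sum(durs + rest_gaps) + final_still
  n <- floor(total * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  accel <- matrix(rep(c(0, 0, GRAVITY_MS2), each = n), n, 3)
  gyro <- matrix(0, n, 3)
  heading <- heading0
  truth <- vector("list", ns)
  for (k in seq_len(ns)) {
    sp <- specs[[k]]
    idx <- which(tt >= starts[k] & tt < starts[k] + sp$duration)
    if (length(idx)) {
      sig <- stride_signal_at(sp, tt[idx] - starts[k], heading)
      accel[idx, ] <- sig$accel
      gyro[idx, ] <- sig$gyro
    }
    disp <- stride_truth_displacement(sp, heading)
    truth[[k]] <- data.frame(
      stride = k, t_start = starts[k], t_end = starts[k] + sp$duration,
      duration = sp$duration, displacement = disp,
      speed = disp / sp$duration)
    heading <- heading + sp$turn_angle
  }
  sig <- add_sensor_noise(list(accel = accel, gyro = gyro),
                          specs[[1L]]$noise)
  rec <- imu_recording(tt, sig$accel, sig$gyro, fs = fs,
                       device_context = device_context,
                       subject_id = subject_id)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(rec = rec, truth = truth)
}
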