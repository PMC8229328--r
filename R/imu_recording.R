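#' Construct an IMU recording
#'
#' Container for a uniformly sampled 6-axis inertial stream from a single
#' foot-worn sensor. All algorithms in the package consume this type.
#' Internally, acceleration is always in m/s^2 (specific force, so a level
#' motionless sensor reads close to +9.81 on the vertical axis) and angular
#' rate in rad/s; times are seconds relative to recording start.
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing on a uniform grid.
#' @param accel numeric matrix, n x 3, accelerometer in m/s^2.
#' @param gyro numeric matrix, n x 3, gyroscope in rad/s.
#' @param fs sampling rate in Hz. If `NULL`, inferred from the median
#'   timestamp spacing.
#' @param device_context `"lab"` or `"home"`; informational.
#' @param subject_id opaque subject label.
#'
#' @return An object of class `imu_recording`: a list with elements
#'   `time`, `accel`, `gyro`, `fs`, `device_context`, `subject_id`.
#' @export
imu_recording <- function(time, accel, gyro, fs = NULL,
                          device_context = c("home", "lab"),
                          subject_id = "unknown") {
  device_context <- match.arg(device_context)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  n <- length(time)
  if (n < 2L)
    stop("insufficient samples: an IMU recording needs at least 2 samples")
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("accel/gyro/time must have the same number of samples")
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("accel and gyro must each have 3 columns")
  dt <- diff(time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  if (fs <= 0) stop("fs must be positive")
  if (any(abs(dt - 1 / fs) > 0.01 / fs)) {
    bad <- which(abs(dt - 1 / fs) > 0.01 / fs)[1L]
    stop(sprintf(
      "non-uniform sampling: spacing %.6f s at sample %d deviates from 1/fs = %.6f s by more than 1%%",
      dt[bad], bad, 1 / fs))
  }
  structure(
    list(time = as.numeric(time), accel = unname(accel),
         gyro = unname(gyro), fs = fs,
         device_context = device_context,
         subject_id = as.character(subject_id)),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> subject=%s context=%s fs=%g Hz n=%d (%.1f s)\n",
    x$subject_id, x$device_context, x$fs, length(x$time),
    x$time[length(x$time)] - x$time[1L]))
  invisible(x)
}

#' Number of samples in an IMU recording
#' @param rec an `imu_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$time)

#' Convert raw channels to internal units
#'
#' Scales accelerometer and gyroscope channels to the package's internal
#' units (m/s^2 and rad/s). The operation is idempotent: a recording whose
#' `unit_spec` is already `"ms2"` / `"rads"` is returned unchanged.
#'
#' @param accel,gyro raw channel matrices.
#' @param accel_unit `"ms2"` (no-op) or `"g"` (multiplied by 9.81).
#' @param gyro_unit `"rads"` (no-op) or `"degs"` (multiplied by pi/180).
#' @return list with rescaled `accel` and `gyro`.
#' @export
normalize_imu_units <- function(accel, gyro,
                                accel_unit = c("ms2", "g"),
                                gyro_unit = c("rads", "degs")) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  if (accel_unit == "g") accel <- accel * GRAVITY_MS2
  if (gyro_unit == "degs") gyro <- gyro * pi / 180
  list(accel = accel, gyro = gyro)
}

# Standard gravity used throughout (m/s^2).
GRAVITY_MS2 <- 9.81

#' Validate still-period gravity magnitude
#'
#' Checks the unit-normalization invariant: over detected still samples the
#' median accelerometer magnitude must be within `tol` of standard gravity.
#' Returns TRUE/FALSE invisibly and warns on failure; recordings with no
#' still samples are vacuously valid.
#'
#' @param rec an `imu_recording` in internal units.
#' @param mask optional logical still mask (from [detect_still()]); when
#'   missing, a default detection is run.
#' @param tol tolerance in m/s^2.
#' @return logical, invisibly.
#' @export
check_gravity_calibration <- function(rec, mask = NULL, tol = 0.5) {
  if (is.null(mask)) mask <- detect_still(rec)$mask
  if (!any(mask)) return(invisible(TRUE))
  mag <- sqrt(rowSums(rec$accel[mask, , drop = FALSE]^2))
  ok <- abs(stats::median(mag) - GRAVITY_MS2) <= tol
  if (!ok)
    warning(sprintf(
      "still-period accelerometer magnitude %.2f m/s^2 deviates from gravity by more than %.2f; check input units",
      stats::median(mag), tol))
  invisible(ok)
}
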