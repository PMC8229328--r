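#' Read an IMU stream from delimited text
#'
#' The package's input dialect is CSV with a mandatory header naming the
#' columns `time, ax, ay, az, gx, gy, gz` (any order; header wins). `time`
#' is seconds. Input units are declared via `accel_unit` / `gyro_unit` and
#' normalized to m/s^2 and rad/s on ingest.
#'
#' @param path CSV file path.
#' @param accel_unit unit of the accelerometer columns: `"ms2"` or `"g"`.
#' @param gyro_unit unit of the gyroscope columns: `"rads"` or `"degs"`.
#' @param fs_hint optional expected sampling rate (Hz); the rate inferred
#'   from the timestamps is cross-checked against it and a mismatch above
#'   5% is an error.
#' @param device_context,subject_id recording metadata.
#' @return an [imu_recording()].
#' @export
read_imu <- function(path, accel_unit = c("ms2", "g"),
                     gyro_unit = c("rads", "degs"), fs_hint = NULL,
                     device_context = c("home", "lab"),
                     subject_id = "unknown") {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  device_context <- match.arg(device_context)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("malformed IMU file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("IMU file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s (non-numeric or missing field)",
                 bad[1L] + 1L, path))
  if (nrow(df) < 2L) stop("insufficient samples in ", path)
  dt <- diff(df$time)
  fs_obs <- 1 / stats::median(dt)
  if (!is.null(fs_hint) && abs(fs_obs - fs_hint) / fs_hint > 0.05)
    stop(sprintf(
      "sampling-rate mismatch: timestamps imply %.2f Hz but fs_hint is %g Hz (>5%%); check units or rate",
      fs_obs, fs_hint))
  gaps <- which(dt > 2.5 / fs_obs)
  if (length(gaps))
    warning(sprintf("%d gap(s) longer than 2 samples detected (first after row %d)",
                    length(gaps), gaps[1L] + 1L))
  ch <- normalize_imu_units(as.matrix(df[c("ax", "ay", "az")]),
                            as.matrix(df[c("gx", "gy", "gz")]),
                            accel_unit, gyro_unit)
  imu_recording(df$time, ch$accel, ch$gyro,
                fs = if (is.null(fs_hint)) round(fs_obs, 6) else fs_hint,
                device_context = device_context, subject_id = subject_id)
}

#' Write an IMU recording to the package's CSV dialect
#'
#' Emits `time,ax,ay,az,gx,gy,gz` in internal units (m/s^2, rad/s) at full
#' double precision, so that `read_imu()` round-trips losslessly.
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu <- function(rec, path) {
  df <- data.frame(time = rec$time,
                   ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
                   gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  lines <- do.call(paste, c(lapply(df, format, digits = 17, trim = TRUE,
                                   scientific = FALSE), sep = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Read a medication diary
#'
#' A diary is a CSV `timestamp,dose_label` with ISO-8601 timestamps (or
#' bare numbers, interpreted as seconds since `t0 = 0`). Events are
#' returned sorted and deduplicated, in seconds relative to `t0`.
#'
#' @param path CSV file path.
#' @param t0 reference epoch defining second zero: a `POSIXct`, an
#'   ISO-8601 string, or a number (seconds).
#' @param tz timezone used to parse character timestamps.
#' @return data.frame with columns `time` (s, numeric) and `dose_label`.
#' @export
read_diary <- function(path, t0 = 0, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (!nrow(df)) {
    warning("empty diary: no intake events")
    return(data.frame(time = numeric(0), dose_label = character(0)))
  }
  if (!all(c("timestamp", "dose_label") %in% names(df)))
    stop("diary must have columns 'timestamp' and 'dose_label'")
  t0s <- .as_seconds(t0, tz)
  secs <- vapply(seq_len(nrow(df)), function(i) {
    s <- tryCatch(.as_seconds(df$timestamp[i], tz), error = function(e) NA_real_)
    if (is.na(s))
      stop(sprintf("unparseable timestamp '%s' in diary row %d",
                   df$timestamp[i], i), call. = FALSE)
    s
  }, numeric(1))
  time <- secs - t0s
  if (any(time < 0))
    warning(sprintf("%d intake(s) before the reference epoch retained with negative time",
                    sum(time < 0)))
  keep <- !duplicated(time)
  out <- data.frame(time = time[keep], dose_label = df$dose_label[keep])
  out[order(out$time), , drop = FALSE]
}

.as_seconds <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  if (is.numeric(x)) return(as.numeric(x))
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  # ISO-8601 date-time, with or without a date part
  p <- suppressWarnings(as.POSIXct(x, tz = tz,
                                   tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                  "%Y-%m-%d %H:%M:%OS",
                                                  "%Y-%m-%dT%H:%M",
                                                  "%Y-%m-%d %H:%M",
                                                  "%H:%M:%OS", "%H:%M")))
  if (is.na(p)) stop("unparseable time: ", x)
  as.numeric(p)
}

#' Read a clinical-scores table
#'
#' CSV keyed by `subject_id` with UPDRS-III totals (`updrs3_on`,
#' `updrs3_off`, each 0-108) and the gait item (`item30_on`, `item30_off`).
#' With `enforce_fluctuation = TRUE`, subjects whose ON/OFF total differs
#' by fewer than 2 points (below the minimal clinically relevant
#' fluctuation) are dropped with a message.
#'
#' @param path CSV path.
#' @param enforce_fluctuation apply the >= 2-point ON/OFF difference filter.
#' @return data.frame of scores.
#' @export
read_clinical_scores <- function(path, enforce_fluctuation = FALSE) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "updrs3_on", "updrs3_off")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical scores missing column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(c("updrs3_on", "updrs3_off"), names(df))) {
    if (any(df[[col]] < 0 | df[[col]] > 108, na.rm = TRUE))
      stop("UPDRS-III totals must lie in 0-108 (column ", col, ")")
  }
  if (enforce_fluctuation) {
    keep <- abs(df$updrs3_on - df$updrs3_off) >= 2
    if (any(!keep))
      message(sum(!keep), " subject(s) dropped: ON/OFF UPDRS-III difference < 2")
    df <- df[keep, , drop = FALSE]
  }
  df
}

#' Write a cohort analysis report
#'
#' Writes the nested result as JSON (`<path>.json`) and the flat
#' lab-vs-home comparison grid as CSV (`<path>.csv`), one row per
#' (lab task x home metric) cell with comparison p, correlation r and p,
#' and R^2 columns.
#'
#' @param results a `cohort_result` from [build_cohort_grid()].
#' @param path output path prefix (without extension).
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(inherits(results, "cohort_result"))
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  jsonlite::write_json(unclass(results), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  grid <- results$grid
  cols <- c("lab_task", "lab_state", "home_state", "metric", "wb_class",
            "stat", "n", "comparison_p", "corr_used", "r", "corr_p",
            "band", "r2", "transform_applied", "flags")
  if (is.null(grid) || !nrow(grid)) {
    grid <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    grid <- grid[intersect(cols, names(grid))]
  }
  utils::write.csv(grid, csv_path, row.names = FALSE, na = "")
  invisible(c(json = json_path, csv = csv_path))
}

#' Write a stride table
#'
#' Per-stride output CSV with columns
#' `subject,trial,t_start,t_end,duration,speed,flags`.
#'
#' @param strides a stride data.frame (see [estimate_strides()]).
#' @param path output CSV path.
#' @param subject,trial labels stamped on every row.
#' @return `path`, invisibly.
#' @export
write_strides <- function(strides, path, subject = "unknown", trial = "") {
  out <- data.frame(subject = subject, trial = trial,
                    t_start = strides$t_start, t_end = strides$t_end,
                    duration = strides$duration, speed = strides$speed,
                    flags = strides$flags)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a stride table written by [write_strides()]
#' @param path CSV path.
#' @return data.frame of strides.
#' @export
read_strides <- function(path) {
  df <- utils::read.csv(path, colClasses = c(flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}
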