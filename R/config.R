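#' Default pipeline configuration
#'
#' Every tunable of the pipeline, grouped by stage, with its default.
#' `io$diary_offset_s` shifts diary times relative to the sensor clock
#' (the two clocks are not synchronized by the protocol; 0 assumes the
#' diary was kept on the recording's time base). State windows are in
#' minutes relative to intake: ON is 60-180 min after a dose, not-ON is
#' the 30 min on either side of a dose.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    io = list(accel_unit = "ms2", gyro_unit = "rads", fs_hint = NULL,
              diary_offset_s = 0),
    stride = list(gyro_thresh = 0.8, accel_band = 0.8, min_still = 0.08,
                  max_stride_duration = 4, max_flat = 0.8, max_speed = 4),
    bouts = list(max_gap_s = 3, min_bout_s = 15, min_speed_ms = 0.2,
                 on_window_min = c(60, 180), noton_window_min = c(-30, 30),
                 overlap_policy = "noton_wins"),
    stats = list(alpha = 0.05, percentile_rule = "linear", transform = "log",
                 mt_correction = "none", min_n = 3),
    seed = NULL,
    verbosity = 1)
}

#' Load a configuration file
#'
#' Reads a YAML key-value file and merges it over [default_config()].
#' Unknown keys at any level are rejected, so typos fail loudly.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @param base configuration to merge into.
#' @return nested named list.
#' @export
load_config <- function(path = NULL, base = default_config()) {
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  merge_config(base, user, "")
}

merge_config <- function(base, user, prefix) {
  if (!length(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                paste0(prefix, k, "."))
    else base[[k]] <- user[[k]]
  }
  base
}

config_stride_params <- function(config) {
  s <- config$stride
  stride_params(gyro_thresh = s$gyro_thresh, accel_band = s$accel_band,
                min_still = s$min_still,
                max_stride_duration = s$max_stride_duration,
                max_flat = s$max_flat, max_speed = s$max_speed)
}
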