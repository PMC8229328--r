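# Shared fixtures and independent oracles, all built in code.

noiseless <- list(accel_sigma = 0, gyro_sigma = 0, gyro_bias = 0)

default_noise <- list(accel_sigma = 0.05, gyro_sigma = 0.01,
                      gyro_bias = 0.005)

# a walk of n identical strides
make_walk <- function(n, stride_length = 1.3, duration = 1.0,
                      noise = noiseless, fs = 128, turn_angle = 0,
                      rest_gaps = 0, seed = NULL) {
  specs <- replicate(n, stride_spec(stride_length, duration,
                                    turn_angle = turn_angle,
                                    noise = noise, fs = fs),
                     simplify = FALSE)
  synth_walk(specs, rest_gaps = rest_gaps, seed = seed)
}

# a stationary recording: gravity + sensor noise only
make_stationary <- function(dur = 5, fs = 128, accel_sigma = 0.05,
                            gyro_sigma = 0.01, seed = 1) {
  set.seed(seed)
  n <- dur * fs
  tt <- (seq_len(n) - 1L) / fs
  accel <- cbind(rnorm(n, 0, accel_sigma), rnorm(n, 0, accel_sigma),
                 rnorm(n, 9.81, accel_sigma))
  gyro <- matrix(rnorm(3 * n, 0, gyro_sigma), n, 3)
  imu_recording(tt, accel, gyro, fs = fs)
}

# exact two-sided Wilcoxon signed-rank p by enumeration over all 2^n sign
# assignments (requires nonzero differences with untied magnitudes),
# mirroring the standard two-sided convention: double the smaller tail.
wilcoxon_enum_p <- function(d) {
  n <- length(d)
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W <- signs %*% r
  mu <- n * (n + 1) / 4
  p <- if (w_obs > mu) mean(W >= w_obs) else mean(W <= w_obs)
  min(1, 2 * p)
}

# brute-force state label: scan every intake window directly
state_oracle <- function(t, intakes, policy = "noton_wins") {
  noton <- any(t >= intakes - 1800 & t < intakes + 1800)
  on <- any(t >= intakes + 3600 & t < intakes + 10800)
  if (noton && on)
    switch(policy, noton_wins = "not_ON", on_wins = "ON", drop = "unlabeled")
  else if (noton) "not_ON"
  else if (on) "ON"
  else "unlabeled"
}

# independent re-integration of noiseless generated signals: rotate by
# strapdown quaternions, double-integrate with the known zero start/end
# velocity, no drift correction beyond the endpoint constraint
reintegrate_displacement <- function(rec, t0, t1) {
  idx <- which(rec$time >= t0 & rec$time <= t1)
  tt <- rec$time[idx]
  q <- c(1, 0, 0, 0)
  a_nav <- matrix(0, length(idx), 3)
  a_nav[1, ] <- freegait:::quat_to_matrix(q) %*% rec$accel[idx[1], ] -
    c(0, 0, 9.81)
  for (j in seq_len(length(idx) - 1L)) {
    dt <- tt[j + 1L] - tt[j]
    rv <- (rec$gyro[idx[j], ] + rec$gyro[idx[j + 1L], ]) / 2 * dt
    q <- freegait:::quat_mul(q, freegait:::quat_from_rotvec(rv))
    a_nav[j + 1L, ] <- freegait:::quat_to_matrix(q) %*%
      rec$accel[idx[j + 1L], ] - c(0, 0, 9.81)
  }
  v <- apply(a_nav, 2, freegait:::cumtrapz_vec, tt = tt)
  ramp <- (tt - tt[1L]) / (tt[length(tt)] - tt[1L])
  v <- v - outer(ramp, v[nrow(v), ])
  disp <- vapply(1:3, function(k) freegait:::trapz_vec(tt, v[, k]),
                 numeric(1))
  sqrt(sum(disp^2))
}
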