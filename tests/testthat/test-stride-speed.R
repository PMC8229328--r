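test_that("still detection handles stationary, walking and spinning inputs", {
  rec <- make_stationary()
  m <- detect_still(rec)
  expect_true(all(m$mask))
  expect_equal(nrow(m$intervals), 1L)

  # constant-rate spin above the gyro threshold
  n <- 500; tt <- (seq_len(n) - 1) / 128
  spin <- imu_recording(tt, matrix(rep(c(0, 0, 9.81), each = n), n, 3),
                        matrix(rep(c(1, 0, 0), each = n), n, 3), fs = 128)
  expect_false(any(detect_still(spin)$mask))

  # detected still time covers the true foot-flat windows
  w <- make_walk(12, duration = 1.1, noise = default_noise, seed = 21)
  m <- detect_still(w$rec)
  flats <- cbind(w$truth$t_start, w$truth$t_start + 0.35 * 1.1)
  covered <- 0
  for (i in seq_len(nrow(flats))) {
    ov <- pmin(m$intervals$t_end, flats[i, 2]) -
      pmax(m$intervals$t_start, flats[i, 1])
    covered <- covered + sum(pmax(ov, 0))
  }
  expect_gte(covered / sum(flats[, 2] - flats[, 1]), 0.9)
})

test_that("noiseless strides are recovered to within 2 cm/s", {
  w <- make_walk(10, stride_length = 1.30, duration = 1.0)
  st <- estimate_strides(w$rec)
  expect_equal(nrow(st), 10L)
  expect_lt(max(abs(st$speed - 1.30)), 0.02)
  expect_equal(st$duration, w$truth$duration, tolerance = 0.02)
})

test_that("a stationary recording yields zero strides", {
  st <- estimate_strides(make_stationary())
  expect_equal(nrow(st), 0L)
})

test_that("speed scales with the velocity profile", {
  w1 <- make_walk(8, stride_length = 0.7, duration = 1.1)
  w2 <- make_walk(8, stride_length = 1.4, duration = 1.1)
  s1 <- estimate_strides(w1$rec)$speed
  s2 <- estimate_strides(w2$rec)$speed
  expect_equal(s2 / s1, rep(2, 8), tolerance = 0.01)
})

test_that("speed strictly increases with stride length at fixed duration", {
  lengths <- c(0.6, 0.9, 1.2, 1.5)
  speeds <- vapply(lengths, function(L) {
    mean(estimate_strides(make_walk(6, stride_length = L,
                                    duration = 1.2)$rec)$speed)
  }, numeric(1))
  expect_true(all(diff(speeds) > 0))
})

test_that("speed is invariant to a global rotation of the sensor frame", {
  set.seed(31)
  w <- make_walk(8, noise = noiseless)
  base <- estimate_strides(w$rec)$speed
  for (rep in 1:3) {
    ang <- runif(3, -pi, pi)
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    R0 <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3) %*%
      matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3) %*%
      matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    rec2 <- w$rec
    rec2$accel <- w$rec$accel %*% t(R0)
    rec2$gyro <- w$rec$gyro %*% t(R0)
    expect_equal(estimate_strides(rec2)$speed, base, tolerance = 1e-6)
  }
})

test_that("velocity is zero at both bounding still samples after dedrift", {
  w <- make_walk(4, noise = default_noise, seed = 41)
  m <- detect_still(w$rec)
  iv <- m$intervals
  for (i in seq_len(nrow(iv) - 1L)) {
    seg <- freegait:::integrate_interval(w$rec, iv, i, iv$end[i],
                                         iv$start[i + 1L])
    expect_lt(seg$v_end, 1e-6)
  }
})

test_that("overlong movement intervals and overspeed strides are handled", {
  # a 5 s continuous movement: no still anchor inside -> no stride emitted
  sp <- stride_spec(2.0, 5.0, swing_fraction = 0.95, noise = noiseless,
                    fs = 128)
  w <- synth_walk(list(sp))
  st <- estimate_strides(w$rec)
  expect_equal(nrow(st), 0L)
})

test_that("lab trials are trimmed to steady state", {
  set.seed(51)
  w <- make_walk(18, stride_length = 1.0, duration = 1.0,
                 noise = default_noise)
  res <- process_lab_trial(lab_trial(w$rec, "straight_normal", "ON"))
  expect_equal(nrow(res$retained), 14L)
  expect_equal(res$n_trimmed, 4L)
  expect_equal(res$mean_speed, 1.0, tolerance = 0.03)
  expect_length(res$flags, 0)

  # 4 detected strides: nothing retained, flagged
  w4 <- make_walk(4)
  res4 <- process_lab_trial(lab_trial(w4$rec, "straight_normal", "ON"))
  expect_equal(nrow(res4$retained), 0L)
  expect_true(is.na(res4$mean_speed))
  expect_true("insufficient_steady_state_strides" %in% res4$flags)
})

test_that("circular-task speeds match the curved-trajectory truth", {
  set.seed(61)
  w <- make_walk(12, stride_length = 0.9, duration = 1.2,
                 turn_angle = 2 * pi / 8, noise = default_noise)
  res <- process_lab_trial(lab_trial(w$rec, "circular_left", "ON"))
  expect_equal(res$mean_speed, mean(w$truth$speed[3:10]), tolerance = 0.05)
})

test_that("fast-pace OFF trials are schema-legal but flagged", {
  w <- make_walk(6)
  tr <- lab_trial(w$rec, "straight_fast", "OFF")
  expect_true("fast_pace_off_state" %in% tr$flags)
})

test_that("strides after a standing rest are flagged and bouts stay apart", {
  specs <- replicate(10, stride_spec(1.2, 1.0, noise = noiseless),
                     simplify = FALSE)
  gaps <- c(rep(0, 4), 10, rep(0, 5))  # 10 s standing after stride 5
  w <- synth_walk(specs, rest_gaps = gaps)
  st <- estimate_strides(w$rec)
  expect_equal(nrow(st), 10L)
  expect_true(grepl("after_rest", st$flags[6]))
  # the flagged stride still carries a sane speed (duration capped)
  expect_lt(abs(st$speed[6] - 1.2), 0.5)
  expect_lt(max(abs(st$speed[-6] - 1.2)), 0.02)
})
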