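test_that("stride truth is analytic and signals re-integrate to it", {
  sp <- stride_spec(1.3, 1.0, noise = noiseless, fs = 128)
  out <- synth_stride_signal(sp)
  expect_equal(out$truth$speed, 1.3)
  expect_equal(out$truth$displacement, 1.3)

  # double integration of the emitted ideal signals recovers displacement
  w <- synth_walk(list(sp))
  disp <- reintegrate_displacement(w$rec, 0, w$truth$t_end[1] + 0.2)
  expect_lt(abs(disp - 1.3), 1e-3)

  # curved stride: chord is shorter than the path
  spc <- stride_spec(0.9, 1.2, turn_angle = 1.0, noise = noiseless)
  wc <- synth_walk(list(spc))
  expect_lt(wc$truth$displacement, 0.9)
  dispc <- reintegrate_displacement(wc$rec, 0, wc$truth$t_end[1] + 0.2)
  expect_lt(abs(dispc - wc$truth$displacement), 1e-3)
})

test_that("a zero-length stride has zero truth speed and is filtered out", {
  sp <- stride_spec(0, 1.0, noise = noiseless)
  w <- synth_walk(list(sp))
  expect_equal(w$truth$speed, 0)
  st <- estimate_strides(w$rec)
  if (nrow(st)) expect_equal(nrow(filter_strides(st)), 0L)
})

test_that("seeding controls noise but not truth", {
  sp <- stride_spec(1.1, 1.0, noise = default_noise)
  a <- synth_stride_signal(sp, seed = 1)
  b <- synth_stride_signal(sp, seed = 2)
  expect_equal(a$truth, b$truth)
  expect_false(identical(a$accel, b$accel))
  c2 <- synth_stride_signal(sp, seed = 1)
  expect_identical(a$accel, c2$accel)
})

test_that("walks assemble into the expected bouts", {
  # 18 contiguous strides -> one bout
  w <- make_walk(18, stride_length = 1.0, duration = 1.0)
  st <- estimate_strides(w$rec)
  expect_equal(nrow(segment_bouts(st, max_gap = 3)), 1L)

  # two 10-stride runs separated by 10 s -> two bouts
  specs <- replicate(20, stride_spec(1.0, 1.0, noise = noiseless),
                     simplify = FALSE)
  gaps <- c(rep(0, 9), 10, rep(0, 10))
  w2 <- synth_walk(specs, rest_gaps = gaps)
  st2 <- estimate_strides(w2$rec)
  expect_equal(nrow(segment_bouts(st2, max_gap = 3)), 2L)
})

test_that("one generated bout per class yields counts (1, 1, 1)", {
  stride_run_times <- function(n, t0) {
    data.frame(t_start = t0 + 0:(n - 1), t_end = t0 + 1:n, speed = 1)
  }
  s <- rbind(stride_run_times(20, 0),      # 20 s -> short
             stride_run_times(45, 100),    # 45 s -> medium
             stride_run_times(70, 300))    # 70 s -> long
  b <- segment_bouts(s, max_gap = 3)
  expect_equal(as.integer(table(b$length_class)[c("short", "medium", "long")]),
               c(1L, 1L, 1L))
})

test_that("mixed-speed signal days round-trip through the estimator", {
  set.seed(91)
  n <- 30
  dur <- runif(n, 0.9, 1.4)
  spd <- runif(n, 0.5, 1.5)
  specs <- lapply(seq_len(n), function(i)
    stride_spec(spd[i] * dur[i], dur[i], noise = default_noise))
  gaps <- ifelse(runif(n) < 0.1, 8, 0)
  w <- synth_walk(specs, rest_gaps = gaps)
  st <- estimate_strides(w$rec)
  expect_equal(nrow(st), n)
  clean <- !grepl("after_rest", st$flags)
  err <- abs(st$speed[clean] - w$truth$speed[clean])
  expect_lt(mean(err), 0.028)
})

test_that("generated days carry complete, deterministic ground truth", {
  d1 <- synth_day(seed = 92)
  d2 <- synth_day(seed = 92)
  expect_identical(d1$strides, d2$strides)
  expect_true(all(c("speed", "state_true", "bout") %in% names(d1$strides)))
  expect_true(all(d1$strides$speed > 0))
  expect_equal(d1$diary$time, day_scenario()$intake_times)
  # stride times are consistent and non-overlapping within bouts
  expect_true(all(d1$strides$t_end > d1$strides$t_start))
})

test_that("drawn bout durations follow the specified log-normal", {
  sc <- day_scenario(duration = 2000 * 3600, intake_times = numeric(0),
                     bout_rate = c(on = 5, noton = 5, unlabeled = 5))
  day <- synth_day(sc, seed = 93, tile_strides = FALSE)
  durs <- day$bouts_true$duration_drawn
  expect_gt(length(durs), 5000)
  ks <- suppressWarnings(
    stats::ks.test(durs, "plnorm", meanlog = log(20), sdlog = 0.8))
  expect_gt(ks$p.value, 0.01)
})

test_that("state-effect nulls are calibrated and real effects detected", {
  # both states share the speed model -> the ON vs not-ON comparison
  # rejects at about the nominal level
  null_sc <- day_scenario(duration = 4 * 3600, intake_times = c(1800, 9000),
                          bout_rate = c(on = 14, noton = 14, unlabeled = 14),
                          k_off = 0.83, resp_mean = 1, resp_sd = 0,
                          p_brisk = 0, p_slow = 0)
  eff_sc <- day_scenario(duration = 4 * 3600, intake_times = c(1800, 9000),
                         bout_rate = c(on = 14, noton = 14, unlabeled = 14),
                         p_brisk = 0, p_slow = 0)
  run_rep <- function(sc, n_subj, seed) {
    set.seed(seed)
    on <- noton <- numeric(n_subj)
    for (s in seq_len(n_subj)) {
      day <- synth_day(sc)
      st <- assign_states(day$strides, day$timeline)
      on[s] <- median(st$speed[st$state == "ON"])
      noton[s] <- median(st$speed[st$state == "not_ON"])
    }
    paired_compare(on, noton)$p
  }
  reps <- 120
  p_null <- vapply(seq_len(reps), function(i) run_rep(null_sc, 12, i),
                   numeric(1))
  expect_lt(abs(mean(p_null < 0.05, na.rm = TRUE) - 0.05), 0.06)

  p_eff <- vapply(seq_len(40), function(i) run_rep(eff_sc, 27, 1000 + i),
                  numeric(1))
  expect_gt(mean(p_eff < 0.05), 0.8)
})
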