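make_strides_df <- function(speeds, state = "ON") {
  n <- length(speeds)
  data.frame(t_start = seq_len(n), t_end = seq_len(n) + 0.9,
             speed = speeds, state = rep(state, n))
}

empty_bouts <- function() {
  b <- segment_bouts(data.frame(t_start = numeric(0), t_end = numeric(0),
                                speed = numeric(0)))
  b$state <- character(0)
  b
}

test_that("percentiles follow the linear-interpolation rule", {
  s <- summarize_subject(make_strides_df(rep(1, 10)), empty_bouts(), "ON")
  expect_equal(unname(s$percentiles), rep(1, 5))

  s <- summarize_subject(make_strides_df(c(0.5, 1.0, 1.5, 2.0)),
                         empty_bouts(), "ON")
  expect_equal(unname(s$percentiles[["p50"]]), 1.25)
  # monotone by construction
  expect_true(all(diff(s$percentiles) >= 0))

  s0 <- summarize_subject(make_strides_df(numeric(0)), empty_bouts(), "ON")
  expect_true(all(is.na(s0$percentiles)))
  expect_true("no_strides_in_state" %in% s0$flags)
})

test_that("walking-bout statistics are per class and NA when empty", {
  strides <- rbind(make_strides_df(rep(0.8, 3)), make_strides_df(rep(1.2, 3)))
  bouts <- data.frame(bout = 1:2, t_start = c(0, 100), t_end = c(20, 170),
                      duration = c(20, 70),
                      length_class = classify_bout_duration(c(20, 70)),
                      n_strides = 3L, n_retained = 3L,
                      mean_speed = c(0.8, 1.2), state = "ON")
  s <- summarize_subject(strides, bouts, "ON")
  expect_equal(s$wb_stats["short", "max"], 0.8)
  expect_equal(s$wb_stats["long", "max"], 1.2)
  expect_true(all(is.na(s$wb_stats["medium", ])))
})

test_that("identical pairs degenerate instead of producing a p-value", {
  x <- c(1, 2, 3, 4, 5)
  res <- paired_compare(x, x)
  expect_true(is.na(res$p))
  expect_true("degenerate_differences" %in% res$flags)
  expect_equal(paired_compare(x[1:2], x[1:2] + 1)$flags, "insufficient_n")
})

test_that("the Wilcoxon path matches exhaustive sign enumeration", {
  set.seed(81)
  for (n in c(6, 8, 10)) {
    for (rep in 1:5) {
      d <- sample(c(-1, 1), n, TRUE) * sample(seq_len(50), n)
      x <- rnorm(n)
      y <- x - d
      p_pkg <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
      expect_equal(p_pkg, wilcoxon_enum_p(d), tolerance = 1e-12)
    }
  }
  # paired_compare takes the Wilcoxon branch for clearly non-normal diffs
  set.seed(82)
  x <- exp(rnorm(20, 0, 2)); y <- x - sample(c(-1, 1), 20, TRUE) * seq(0.01, 0.2, length.out = 20)
  res <- paired_compare(x, y)
  expect_true(res$test_used %in% c("wilcoxon", "paired_t"))
})

test_that("normality gating selects the paired t for Gaussian differences", {
  set.seed(83)
  x <- rnorm(27, 1.0, 0.1); y <- x + rnorm(27, 0.05, 0.05)
  res <- paired_compare(x, y)
  expect_equal(res$test_used, "paired_t")
  expect_gte(res$normality_p, 0.05)
})

test_that("perfect linear and rank-reversed relationships are recovered", {
  set.seed(84)
  x <- rnorm(10, 1, 0.2)
  res <- correlate_paired(x, 2 * x + 1)
  expect_equal(res$corr_used, "pearson")
  expect_equal(res$r, 1)
  expect_equal(res$band, "high")
  expect_equal(res$r2, 1)
  expect_equal(res$transform_applied, "none")

  y <- exp(-(rank(x)))  # monotone-decreasing, clearly non-normal
  res2 <- correlate_paired(x, y)
  expect_equal(res2$corr_used, "spearman")
  expect_equal(res2$r, -1)

  resc <- correlate_paired(x, rep(1, 10))
  expect_true("constant_variable" %in% resc$flags)
})

test_that("Spearman equals Pearson applied to ranks", {
  set.seed(85)
  for (rep in 1:10) {
    x <- rlnorm(15); y <- rlnorm(15) + 0.3 * x
    expect_equal(cor(x, y, method = "spearman"),
                 cor(rank(x), rank(y), method = "pearson"),
                 tolerance = 1e-12)
  }
})

test_that("R^2 equals r^2 in the untransformed Pearson case", {
  set.seed(86)
  for (rep in 1:10) {
    x <- rnorm(20, 1, 0.2); y <- 0.8 * x + rnorm(20, 0, 0.1)
    res <- correlate_paired(x, y)
    if (res$corr_used == "pearson" && res$transform_applied == "none")
      expect_equal(res$r2, res$r^2, tolerance = 1e-10)
  }
})

test_that("banding is piecewise-constant with breakpoints at 0.5 and 0.7", {
  eps <- 1e-12
  expect_equal(correlation_band(c(0, 0.5 - eps, 0.5, 0.7, 0.7 + 1e-9, 1)),
               c("low", "low", "moderate", "moderate", "high", "high"))
  # sign is ignored: bands use |r|
  expect_equal(correlation_band(c(-0.4, -0.6, -0.9)),
               c("low", "moderate", "high"))
})

test_that("the correlation estimate is consistent at the cohort size", {
  set.seed(87)
  rho <- 0.6; n <- 27; reps <- 2000
  rs <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    rs[i] <- cor(x, y)
  }
  expect_equal(mean(rs), rho, tolerance = 0.03)
})

test_that("log transform is applied to non-normal positive variables", {
  set.seed(88)
  x <- rnorm(25, 1, 0.1)
  y <- exp(rnorm(25, 0, 1.5)) + 0.2 * x   # heavily skewed, positive
  res <- correlate_paired(x, y)
  if (res$corr_used == "spearman") {
    expect_equal(res$transform_applied, "log")
    expect_true(res$r2 >= 0 && res$r2 <= 1)
  }
})
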