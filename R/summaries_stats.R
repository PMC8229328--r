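#' Per-subject, per-state gait-speed summary
#'
#' Implements both distributional views of free-living gait speed: the
#' percentile approach (25th, 50th, 75th, 90th percentiles and maximum
#' over all retained gait cycles) and the walking-bout approach (25th,
#' 50th percentile and maximum of per-bout mean speeds within each bout
#' length class). Percentiles use linear interpolation between closest
#' ranks (the type-7 rule).
#'
#' @param strides state-labeled stride data.frame (`speed`, `state`).
#' @param bouts state-labeled bout table from [segment_bouts()] +
#'   [assign_states()].
#' @param state which state to summarize: `"ON"` or `"not_ON"`.
#' @param min_speed stride speed floor (m/s) applied before summarizing.
#' @param subject_id label carried into the output.
#' @return object of class `speed_summary`: list with `percentiles`
#'   (named numeric: p25, p50, p75, p90, max), `wb_stats` (3 x 3 matrix,
#'   rows short/medium/long, cols p25/p50/max; NA where a class is
#'   empty), `n_strides`, `n_bouts` (per class), `state`, `flags`.
#' @export
summarize_subject <- function(strides, bouts, state = c("ON", "not_ON"),
                              min_speed = 0.2, subject_id = "unknown") {
  state <- match.arg(state)
  flags <- character(0)
  sp <- strides$speed[strides$state == state]
  sp <- sp[!is.na(sp) & sp >= min_speed]
  if (length(sp)) {
    q <- stats::quantile(sp, c(0.25, 0.5, 0.75, 0.9), type = 7,
                         names = FALSE)
    percentiles <- c(p25 = q[1], p50 = q[2], p75 = q[3], p90 = q[4],
                     max = max(sp))
  } else {
    percentiles <- c(p25 = NA_real_, p50 = NA_real_, p75 = NA_real_,
                     p90 = NA_real_, max = NA_real_)
    flags <- c(flags, "no_strides_in_state")
  }
  wb <- matrix(NA_real_, 3, 3,
               dimnames = list(WB_CLASSES, c("p25", "p50", "max")))
  n_bouts <- setNames(integer(3), WB_CLASSES)
  b <- bouts[bouts$state == state &
               as.character(bouts$length_class) %in% WB_CLASSES &
               !is.na(bouts$mean_speed), , drop = FALSE]
  for (cl in WB_CLASSES) {
    ms <- b$mean_speed[as.character(b$length_class) == cl]
    n_bouts[cl] <- length(ms)
    if (length(ms))
      wb[cl, ] <- c(stats::quantile(ms, c(0.25, 0.5), type = 7,
                                    names = FALSE), max(ms))
  }
  structure(list(subject_id = subject_id, state = state,
                 percentiles = percentiles, wb_stats = wb,
                 n_strides = length(sp), n_bouts = n_bouts, flags = flags),
            class = "speed_summary")
}

#' @export
print.speed_summary <- function(x, ...) {
  cat(sprintf("<speed_summary> %s @ %s: %d strides\n", x$subject_id,
              x$state, x$n_strides))
  print(round(x$percentiles, 3))
  invisible(x)
}

# Shapiro-Wilk p-value with the test's domain guarded; NA when the sample
# is degenerate (constant or n < 3). n > 5000 is decimated evenly.
shapiro_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || diff(range(x)) == 0) return(NA_real_)
  if (length(x) > 5000L)
    x <- x[round(seq(1L, length(x), length.out = 5000L))]
  stats::shapiro.test(x)$p.value
}

#' Normality-gated paired comparison
#'
#' Tests a paired difference: Shapiro-Wilk on the paired differences at
#' `alpha` selects a paired t-test (normal) or a Wilcoxon signed-rank
#' test (otherwise). Pairs with a missing member are dropped.
#'
#' @param x,y paired numeric samples.
#' @param alpha significance level of the normality gate.
#' @return list: `test_used` (`"paired_t"` / `"wilcoxon"` / NA), `p`,
#'   `normality_p`, `n`, `flags`.
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(test_used = NA_character_, p = NA_real_,
                normality_p = NA_real_, n = n, flags = "insufficient_n"))
  d <- x - y
  if (diff(range(d)) == 0) {
    return(list(test_used = if (all(d == 0)) "wilcoxon" else "paired_t",
                p = NA_real_, normality_p = NA_real_, n = n,
                flags = "degenerate_differences"))
  }
  np <- shapiro_p(d)
  if (!is.na(np) && np >= alpha) {
    list(test_used = "paired_t",
         p = stats::t.test(x, y, paired = TRUE)$p.value,
         normality_p = np, n = n, flags = character(0))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE)$p.value)
    list(test_used = "wilcoxon", p = p, normality_p = np, n = n,
         flags = character(0))
  }
}

#' Correlation strength band
#'
#' Piecewise-constant banding of a correlation coefficient by magnitude:
#' below 0.5 is low, 0.5 to 0.7 is moderate, above 0.7 is high.
#'
#' @param r correlation coefficient(s).
#' @return character vector `"low"` / `"moderate"` / `"high"`.
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  ifelse(is.na(a), NA_character_,
         ifelse(a < 0.5, "low", ifelse(a <= 0.7, "moderate", "high")))
}

#' Normality-gated correlation with banding and R-squared
#'
#' Shapiro-Wilk is run on each variable: Pearson correlation is used when
#' both pass at `alpha`, Spearman otherwise. The coefficient of
#' determination comes from a straight-line fit of `y` on `x` after
#' natural-log transforming any variable that failed normality (speeds
#' are positive; a non-positive value suppresses the transform with a
#' flag).
#'
#' @param x predictor sample (e.g. lab speed per subject).
#' @param y response sample (e.g. home speed per subject).
#' @param alpha significance level of the normality gate.
#' @return list: `corr_used` (`"pearson"` / `"spearman"`), `r`, `corr_p`,
#'   `band`, `r2`, `transform_applied` (`"none"` / `"log"`),
#'   `normality_p_x`, `normality_p_y`, `n`, `flags`.
#' @export
correlate_paired <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  empty <- list(corr_used = NA_character_, r = NA_real_, corr_p = NA_real_,
                band = NA_character_, r2 = NA_real_,
                transform_applied = NA_character_,
                normality_p_x = NA_real_, normality_p_y = NA_real_,
                n = n, flags = character(0))
  if (n < 3L) { empty$flags <- "insufficient_n"; return(empty) }
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    empty$flags <- "constant_variable"; return(empty)
  }
  px <- shapiro_p(x); py <- shapiro_p(y)
  normal_x <- !is.na(px) && px >= alpha
  normal_y <- !is.na(py) && py >= alpha
  if (normal_x && normal_y) {
    ct <- stats::cor.test(x, y, method = "pearson")
    used <- "pearson"
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    used <- "spearman"
  }
  transform <- "none"
  xt <- x; yt <- y
  flags <- character(0)
  if (!normal_x || !normal_y) {
    to_transform <- c(if (!normal_x) x, if (!normal_y) y)
    if (all(to_transform > 0)) {
      if (!normal_x) xt <- log(x)
      if (!normal_y) yt <- log(y)
      transform <- "log"
    } else {
      flags <- c(flags, "nonpositive_values_transform_skipped")
    }
  }
  fit <- stats::lm(yt ~ xt)
  r2 <- 1 - sum(fit$residuals^2) / sum((yt - mean(yt))^2)
  list(corr_used = used, r = unname(ct$estimate), corr_p = ct$p.value,
       band = correlation_band(unname(ct$estimate)),
       r2 = r2, transform_applied = transform,
       normality_p_x = px, normality_p_y = py, n = n, flags = flags)
}
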