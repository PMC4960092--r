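#' Least-squares linear regression with Pearson correlation
#'
#' Ordinary least squares of `y` on `x` plus the Pearson correlation. A
#' constant `y` is handled by convention (slope 0, r 0); a constant `x` is
#' a degenerate input and errors.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return A list: `slope`, `intercept`, `r`, `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y))
    stop("linear_regression: x and y lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("linear_regression: need n >= 3", call. = FALSE)
  if (sd(x) == 0)
    stop("linear_regression: x is constant (degenerate input)", call. = FALSE)
  fit <- lm(y ~ x)
  r <- if (sd(y) == 0) 0 else cor(x, y)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, n = length(x))
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' `z = atanh(r)` is approximately normal with SE `1 / sqrt(n - 3)`; the CI
#' is `tanh(z -/+ z_crit / sqrt(n - 3))` with `z_crit = qnorm(1 - alpha/2)`
#' (1.959964 at the 95 % level).
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @param n number of pairs, n >= 4.
#' @param level confidence level.
#' @return A list: `r`, `ci_low`, `ci_high`, `n`, `level`.
#' @export
#' @examples
#' pearson_ci(0.825, 10)$ci_high  # 0.957
pearson_ci <- function(r, n, level = 0.95) {
  if (abs(r) >= 1)
    stop("pearson_ci: |r| must be < 1 (degenerate)", call. = FALSE)
  if (n < 4L) stop("pearson_ci: need n >= 4", call. = FALSE)
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - hw), ci_high = tanh(z + hw),
       n = n, level = level)
}

#' Bland-Altman method comparison
#'
#' Paired-difference analysis: differences `d = a - b`, bias `mean(d)`,
#' limits of agreement `bias +/- 1.96 sd(d)` (sample SD, n - 1 denominator;
#' the multiplier is exactly 1.96, not a t quantile). Confidence intervals
#' use the large-sample standard errors `SE_bias = sd / sqrt(n)` and
#' `SE_loa = sd * sqrt(3 / n)` with the t(n - 1) quantile.
#'
#' @param a,b paired measurements (same length, n >= 2). Differences are
#'   `a - b`.
#' @param level confidence level for the CIs.
#' @return A list of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `ci_bias`, `ci_loa_low`, `ci_loa_high` (length-2 vectors),
#'   `n`, `means`, `diffs`.
#' @export
bland_altman <- function(a, b, level = 0.95) {
  if (length(a) != length(b))
    stop("bland_altman: a and b lengths differ", call. = FALSE)
  if (length(a) < 2L)
    stop("bland_altman: need n >= 2", call. = FALSE)
  d <- a - b
  out <- bland_altman_summary(mean(d), sd(d), n = length(d), level = level)
  out$means <- (a + b) / 2
  out$diffs <- d
  out
}

#' Bland-Altman limits from printed summary statistics
#'
#' Reconstructs the limits of agreement (and, when `n` is given, their CIs)
#' from a reported bias and SD of differences, so published comparisons can
#' be reproduced without per-subject data.
#'
#' @param bias mean difference.
#' @param sd_diff sample SD of differences.
#' @param n number of pairs (optional; needed for CIs).
#' @param level confidence level.
#' @return Same structure as [bland_altman()] (without `means`/`diffs`).
#' @export
#' @examples
#' bland_altman_summary(-54.3, 38.5)$loa_low   # -129.8 mL/s
#' bland_altman_summary(-132.0, 40.4)$loa_low  # -211.2 mL/s
bland_altman_summary <- function(bias, sd_diff, n = NULL, level = 0.95) {
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  ci_bias <- ci_lo <- ci_hi <- c(NA_real_, NA_real_)
  if (!is.null(n) && n >= 2) {
    tcrit <- qt(1 - (1 - level) / 2, df = n - 1)
    se_bias <- sd_diff / sqrt(n)
    se_loa <- sd_diff * sqrt(3 / n)
    ci_bias <- bias + c(-1, 1) * tcrit * se_bias
    ci_lo <- loa_low + c(-1, 1) * tcrit * se_loa
    ci_hi <- loa_high + c(-1, 1) * tcrit * se_loa
  }
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 ci_bias = ci_bias, ci_loa_low = ci_lo, ci_loa_high = ci_hi,
                 n = n %||% NA_integer_, level = level),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.2f (SD %.2f), LoA [%.2f, %.2f], n = %s\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' Single-measure ICC from the two-way mean-square decomposition of a
#' complete subjects x raters table. `ICC(2,1)` (two-way random effects,
#' absolute agreement) is the default; `ICC(3,1)` (two-way mixed,
#' consistency) is also available. With `MSR`, `MSC`, `MSE` the subject,
#' rater and residual mean squares, n subjects and k raters:
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' \deqn{ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE)}
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns,
#'   complete (no NA), >= 2 rows and >= 2 columns.
#' @param form `"ICC2_1"` (absolute agreement) or `"ICC3_1"` (consistency).
#' @return A list of class `icc_result`: `icc`, `form`, `n_subjects`,
#'   `n_raters`, and the mean squares.
#' @export
icc <- function(ratings, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop("icc: ratings table is incomplete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop("icc: need >= 2 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- switch(form,
    ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3_1 = (msr - mse) / (msr + (k - 1) * mse))
  structure(list(icc = val, form = form, n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across two
#' or more groups, via [stats::oneway.test()]. Zero within-group variance
#' with unequal group means (an infinite F) is refused as a degenerate
#' input.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return A list: `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L)
    stop("one_way_anova: need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("one_way_anova: every group needs >= 2 values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  means <- vapply(groups, mean, numeric(1))
  if (ssw == 0 && max(means) > min(means))
    stop("one_way_anova: zero within-group variance with unequal means ",
         "(F is unbounded)", call. = FALSE)
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  list(f = unname(ft$statistic), p = unname(ft$p.value),
       df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]))
}

#' Relative underestimation of a test method against a reference
#'
#' `100 (reference - test) / reference` percent, reported raw and rounded
#' to the nearest integer percent.
#'
#' @param reference_mean reference-method mean (must be positive).
#' @param test_mean test-method mean.
#' @return A list: `percent` (raw), `percent_rounded`.
#' @export
#' @examples
#' relative_underestimation(467.3, 413.1)$percent_rounded  # 12
relative_underestimation <- function(reference_mean, test_mean) {
  if (reference_mean <= 0)
    stop("relative_underestimation: reference mean must be positive",
         call. = FALSE)
  p <- 100 * (reference_mean - test_mean) / reference_mean
  list(percent = p, percent_rounded = round(p))
}
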