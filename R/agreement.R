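# Method-comparison statistics for paired Cobb angle measurements:
# Bland-Altman, ICC(2,1) with confidence interval, MAD/MAE summaries.

check_paired <- function(a, b, min_n = 2L) {
  if (length(a) != length(b))
    st_domain_error("paired measurement vectors must have equal length")
  if (length(a) < min_n)
    st_domain_error(sprintf("at least %d measurement pairs are required", min_n))
  if (any(!is.finite(a)) || any(!is.finite(b)))
    st_domain_error("measurements must all be finite")
  invisible(NULL)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same quantity by two methods, analyzes
#' the differences `d_i = a_i - b_i`: the bias is `mean(d)`, and the 95%
#' limits of agreement are `bias +/- 1.96 * sd(d)` with the sample (n-1)
#' standard deviation. The per-pair means and differences are returned as
#' plot-ready coordinates.
#'
#' @param a,b Numeric vectors of paired measurements (degrees), length >= 2.
#' @return A list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`, and
#'   a data frame `points` with columns `mean` and `difference`.
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 18, 33))
#' @export
bland_altman <- function(a, b) {
  check_paired(a, b, 2L)
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  list(bias = bias,
       loa_low = bias - 1.96 * sd_diff,
       loa_high = bias + 1.96 * sd_diff,
       sd_diff = sd_diff,
       n = length(d),
       points = data.frame(mean = (a + b) / 2, difference = d))
}

#' Intraclass correlation ICC(2,1) with confidence interval
#'
#' Two-way random effects, absolute agreement, single measurement -- the
#' standard ICC form for method-agreement studies with two raters. The
#' point estimate comes from the two-way ANOVA mean squares
#' (subjects x raters), and the confidence interval from the F
#' distribution with Satterthwaite degrees of freedom, following McGraw &
#' Wong's single-score absolute-agreement formulas.
#'
#' @param a,b Numeric vectors of paired measurements, length >= 3.
#' @param confidence Confidence level, default 0.95.
#' @return A list with `icc`, `ci_low`, `ci_high`, `confidence`, `n`, and
#'   the mean squares `msr` (rows/subjects), `msc` (columns/raters),
#'   `mse` (error).
#' @export
icc_2_1 <- function(a, b, confidence = 0.95) {
  check_paired(a, b, 3L)
  x <- cbind(a, b)
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  if (sum((x - gm)^2) == 0)
    st_domain_error("ICC undefined: zero total variance (all values identical)")
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((x - gm)^2) - k * sum((row_m - gm)^2) - n * sum((col_m - gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - confidence
  if (abs(1 - icc) < 1e-12) {
    # perfect agreement: the interval degenerates
    ci <- c(icc, icc)
  } else {
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(n * (msr - f_l * mse) /
              (f_l * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (f_u * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * f_u * msr))
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], confidence = confidence,
       n = n, msr = msr, msc = msc, mse = mse)
}

#' Summary of absolute paired differences: MAD, MAE, and their SD
#'
#' With `u_i = |a_i - b_i|`: MAD is the median of `u` (the median absolute
#' difference between the two methods), MAE the mean of `u`, and the
#' companion SD is the sample (n-1) standard deviation of `u`.
#'
#' @param a,b Numeric vectors of paired measurements, length >= 2.
#' @return A list with `mad`, `mae`, `sd_abs_diff`, `n`.
#' @export
paired_error_summary <- function(a, b) {
  check_paired(a, b, 2L)
  u <- abs(a - b)
  list(mad = stats::median(u), mae = mean(u), sd_abs_diff = stats::sd(u),
       n = length(u))
}

#' Classic one-sample median absolute deviation (unscaled)
#'
#' The median of absolute deviations from the median,
#' `median(|x - median(x)|)`, without the consistency constant. This is
#' the one-sample dispersion statistic sometimes also called "MAD"; for
#' paired method comparison, [paired_error_summary()]'s `mad` (median of
#' absolute paired differences) is the quantity reported alongside MAE.
#'
#' @param x A numeric vector.
#' @return The unscaled median absolute deviation.
#' @export
mad_from_median <- function(x) stats::mad(x, constant = 1)

#' Full agreement report for two measurement methods
#'
#' Combines [bland_altman()], [icc_2_1()], and [paired_error_summary()]
#' into the flat report structure used by the CSV export: bias and limits
#' of agreement, ICC with confidence interval, MAD and MAE with the SD of
#' the absolute differences, and the SD of the signed differences.
#'
#' @param a,b Numeric vectors of paired measurements, length >= 3.
#' @param confidence Confidence level for the ICC interval, default 0.95.
#' @return A list of class `agreement_report` with fields `bias, loa_low,
#'   loa_high, sd_diff, icc, icc_ci, mad, mae, sd_abs_diff, n`, plus
#'   `points` for Bland-Altman plotting.
#' @export
agreement_report <- function(a, b, confidence = 0.95) {
  ba <- bland_altman(a, b)
  icc <- icc_2_1(a, b, confidence)
  es <- paired_error_summary(a, b)
  structure(list(bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 sd_diff = ba$sd_diff, icc = icc$icc,
                 icc_ci = c(icc$ci_low, icc$ci_high),
                 mad = es$mad, mae = es$mae, sd_abs_diff = es$sd_abs_diff,
                 n = ba$n, points = ba$points),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  bias %.3f deg, limits of agreement [%.3f, %.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  ICC(2,1) %.3f (95%% CI %.3f-%.3f)\n",
              x$icc, x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  MAD %.2f deg, MAE %.2f deg (SD of |diff| %.2f)\n",
              x$mad, x$mae, x$sd_abs_diff))
  invisible(x)
}
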