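#' Method agreement between estimated and invasive ICP
#'
#' Bland-Altman analysis of paired measurements. Differences are oriented
#' `estimated - invasive` throughout. Reports the mean and standard
#' deviation (n - 1 denominator) of the differences, the 95% limits of
#' agreement `mean +/- 1.96 sd`, the half-width of the 95% confidence
#' interval on each limit using the large-sample approximation
#' `1.96 * sd * sqrt(3 / n)`, the mean absolute difference, the OLS slope
#' and Pearson correlation of estimated on invasive, moment skewness and
#' kurtosis (Pearson convention, normal = 3) of the differences, and a
#' delegated Shapiro-Wilk normality test.
#'
#' @param pairs data frame with numeric columns `invasive` and `estimated`
#'   (mmHg); other columns (e.g. `subject_id`, `method`, `posture`) are
#'   carried along untouched.
#' @return An object of class `"icp_agreement"` with elements `n`,
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `loa_ci_halfwidth`,
#'   `mean_abs_diff`, `slope`, `intercept`, `r`, `skewness`, `kurtosis`,
#'   `shapiro_w`, `shapiro_p`, `pairs`, `differences`.
#' @examples
#' set.seed(1)
#' inv <- runif(30, 5, 30)
#' agreement(data.frame(invasive = inv, estimated = inv + rnorm(30, 0, 3.2)))
#' @export
agreement <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("invasive", "estimated") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$invasive) & is.finite(pairs$estimated), ,
                 drop = FALSE]
  n <- nrow(pairs)
  if (n < 3) stop("insufficient data: need at least 3 complete pairs")
  d <- pairs$estimated - pairs$invasive
  m <- mean(d)
  s <- stats::sd(d)
  m2 <- mean((d - m)^2)
  skew <- if (m2 > 0) mean((d - m)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((d - m)^4) / m2^2 else NA_real_
  fit <- stats::lm(estimated ~ invasive, data = pairs)
  sw <- tryCatch(stats::shapiro.test(d),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  structure(
    list(n = n, mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         loa_ci_halfwidth = 1.96 * s * sqrt(3 / n),
         mean_abs_diff = mean(abs(d)),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = stats::cor(pairs$invasive, pairs$estimated),
         skewness = skew, kurtosis = kurt,
         shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
         pairs = pairs, differences = d),
    class = "icp_agreement")
}

#' @export
print.icp_agreement <- function(x, ...) {
  cat(sprintf("ICP method agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  mean difference (estimated - invasive): %.2f mmHg (sd %.2f)\n",
              x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% limits of agreement: %.2f to %.2f mmHg (CI half-width %.2f)\n",
              x$loa_low, x$loa_high, x$loa_ci_halfwidth))
  cat(sprintf("  mean absolute difference: %.2f mmHg\n", x$mean_abs_diff))
  cat(sprintf("  estimated ~ invasive: slope %.2f, r = %.2f\n", x$slope, x$r))
  cat(sprintf("  differences: skewness %.2f, kurtosis %.2f (normal = 3), Shapiro-Wilk W = %.2f (p = %.3g)\n",
              x$skewness, x$kurtosis, x$shapiro_w, x$shapiro_p))
  invisible(x)
}

#' Plot method agreement
#'
#' @param x an [agreement()] result.
#' @param y ignored.
#' @param which `"blandaltman"` (difference against mean, with the bias and
#'   limits of agreement), `"scatter"` (estimated against invasive with the
#'   regression and unity lines) or `"hist"` (difference histogram).
#' @param ... passed to the underlying plot.
#' @export
plot.icp_agreement <- function(x, y,
                               which = c("blandaltman", "scatter", "hist"),
                               ...) {
  which <- match.arg(which)
  p <- x$pairs
  d <- x$differences
  if (which == "blandaltman") {
    avg <- (p$estimated + p$invasive) / 2
    graphics::plot(avg, d, xlab = "Mean of invasive and estimated ICP (mmHg)",
                   ylab = "Estimated - invasive (mmHg)", pch = 19, ...)
    graphics::abline(h = x$mean_diff, col = "blue")
    graphics::abline(h = c(x$loa_low, x$loa_high), col = "red3", lty = 2)
  } else if (which == "scatter") {
    graphics::plot(p$invasive, p$estimated, xlab = "Invasive ICP (mmHg)",
                   ylab = "Estimated ICP (mmHg)", pch = 19, ...)
    graphics::abline(x$intercept, x$slope, col = "blue")
    graphics::abline(0, 1, col = "black", lty = 2)
  } else {
    graphics::hist(d, xlab = "Estimated - invasive (mmHg)", main = "", ...)
  }
  invisible(x)
}

#' Sensitivity and specificity at an ICP cut-off
#'
#' Condition positive means invasive ICP strictly above `cutoff`; test
#' positive means estimated ICP strictly above `cutoff`. Undefined rates
#' (zero denominator) are returned as `NaN` with the corresponding flag
#' set.
#'
#' @param pairs data frame with columns `invasive` and `estimated` (mmHg).
#' @param cutoff ICP threshold in mmHg (e.g. 14.7 for borderline, 18.4 for
#'   pathological elevation).
#' @return List with `sensitivity`, `specificity`, the confusion counts
#'   `tp`, `fp`, `tn`, `fn`, `cutoff`, and flags
#'   `sensitivity_undefined` / `specificity_undefined`.
#' @export
diagnostic_performance <- function(pairs, cutoff) {
  stopifnot(all(c("invasive", "estimated") %in% names(pairs)),
            nrow(pairs) >= 1, is.finite(cutoff))
  cond <- pairs$invasive > cutoff
  test <- pairs$estimated > cutoff
  tp <- sum(cond & test); fn <- sum(cond & !test)
  tn <- sum(!cond & !test); fp <- sum(!cond & test)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
       tp = tp, fp = fp, tn = tn, fn = fn, cutoff = cutoff,
       sensitivity_undefined = tp + fn == 0,
       specificity_undefined = tn + fp == 0)
}

#' Sample size for a target limits-of-agreement confidence interval
#'
#' Smallest number of paired subjects `n` such that the 95% confidence
#' interval on each Bland-Altman limit of agreement,
#' `+/- 1.96 * sd * sqrt(3 / n)`, is no wider than `ci_halfwidth`:
#' `n = ceiling(3 * (1.96 * sd_diff / ci_halfwidth)^2)`.
#'
#' @param sd_diff anticipated standard deviation of the paired differences,
#'   mmHg (> 0).
#' @param ci_halfwidth target confidence-interval half-width, mmHg (> 0).
#' @return Required sample size (integer).
#' @examples
#' loa_sample_size(3.8, 2.5)  # 27
#' @export
loa_sample_size <- function(sd_diff, ci_halfwidth) {
  if (!is.finite(sd_diff) || sd_diff <= 0)
    stop("parameter error: sd_diff must be > 0")
  if (!is.finite(ci_halfwidth) || ci_halfwidth <= 0)
    stop("parameter error: ci_halfwidth must be > 0")
  as.integer(ceiling(3 * (1.96 * sd_diff / ci_halfwidth)^2))
}

#' Proportion of paired differences inside an interval
#'
#' @param pairs data frame with columns `invasive` and `estimated` (mmHg).
#' @param low,high interval bounds in mmHg (inclusive); an empty interval
#'   (`low > high`) gives 0.
#' @return Proportion of differences `estimated - invasive` within
#'   `[low, high]`.
#' @export
fraction_within <- function(pairs, low, high) {
  stopifnot(all(c("invasive", "estimated") %in% names(pairs)),
            nrow(pairs) >= 1)
  d <- pairs$estimated - pairs$invasive
  mean(d >= low & d <= high)
}
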