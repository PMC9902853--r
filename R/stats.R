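# Longitudinal statistics: percentage change, annualization, paired tests,
# correlation, Bland-Altman agreement, paired-t power and sample size.

#' Percentage change between two scan sessions
#'
#' `(followup / baseline - 1) * 100`, the standard longitudinal change
#' measure for DVR, SUVr and R1.
#'
#' @param baseline,followup Numeric vectors (baseline values must be
#'   positive).
#' @return Percentage change (vectorized).
#' @examples
#' percentage_change(1.045, 1.075)  # 2.87
#' @export
percentage_change <- function(baseline, followup) {
  if (!is.numeric(baseline) || !is.numeric(followup))
    stop("inputs must be numeric")
  if (any(baseline <= 0)) stop("baseline values must be positive")
  (followup / baseline - 1) * 100
}

#' Annualized percentage change
#'
#' @param pct_change Percentage change over the scan interval.
#' @param interval Interval between sessions (years, > 0).
#' @return Percent per year.
#' @export
annualized_change <- function(pct_change, interval) {
  if (any(interval <= 0)) stop("interval must be positive (years)")
  pct_change / interval
}

#' Two-sided paired t test
#'
#' Thin wrapper around [stats::t.test()] returning the statistic and
#' p-value.  Identical vectors (all differences zero) return `t = 0`,
#' `p = 1`; zero-variance differences with non-zero mean are an error.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `t_stat`, `p_value`, `df`, `n`.
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))  # diffs 1,2,3: t = 3.46, p = 0.074
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t_stat = 0, p_value = 1, df = length(d) - 1L,
                  n = length(d)))
    stop("differences have zero variance but non-zero mean")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), n = length(d))
}

#' Pearson correlation with t-based p-value
#'
#' Thin wrapper around [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no defined correlation")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean paired difference `method_a - method_b` (convention:
#' quantitative minus semiquantitative, i.e. DVR change minus SUVr change);
#' limits of agreement are `bias +/- 1.96 sd(differences)`.
#'
#' @param method_a,method_b Numeric vectors of equal length >= 2.
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n_pairs`, plus the paired `means` and `diffs` for
#'   plotting.
#' @examples
#' bland_altman(c(2.56, 2.82, 2.33), c(1.85, 2.47, 2.17))$bias  # 0.41
#' @export
bland_altman <- function(method_a, method_b) {
  if (length(method_a) != length(method_b))
    stop("method vectors must have equal length")
  if (length(method_a) < 2L) stop("need at least 2 pairs")
  d <- method_a - method_b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 n_pairs = length(d),
                 means = (method_a + method_b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman agreement over", x$n_pairs, "pairs\n")
  cat("  bias =", format(x$bias, digits = digits),
      " (SD of differences =", format(x$sd_diff, digits = digits), ")\n")
  cat("  95% limits of agreement: [",
      format(x$loa_low, digits = digits), ",",
      format(x$loa_high, digits = digits), "]\n")
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ..., xlab = "Mean of methods",
                              ylab = "Difference (a - b)") {
  graphics::plot(x$means, x$diffs, pch = 16, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c(2, 1, 1))
  invisible(x)
}

#' Power of the two-sided one-sample (paired) t test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `dz * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param n Number of pairs (>= 2).
#' @param dz Standardized effect size (mean change / SD of change).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1); equals `alpha` at `dz = 0`.
#' @export
power_paired <- function(n, dz, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- dz * sqrt(n)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp,
                                         lower.tail = FALSE)
}

#' Required sample size for a paired t test
#'
#' Smallest `n >= 2` such that the two-sided paired t test at level
#' `alpha` reaches the requested power for the standardized effect
#' `dz = mean_change / sd_change`, scanning `n` upward against the exact
#' noncentral-t power ([power_paired()]).  The effect is given as a mean
#' and SD of percentage change, matching how expected change in tracer
#' retention is specified for longitudinal designs.
#'
#' @param mean_change Expected percentage change (non-zero).
#' @param sd_change SD of the percentage change (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Requested power (default 0.80).
#' @param n_max Scan cap (error if exceeded).
#' @return Object of class `sample_size_result`: `expected_pct_change`,
#'   `sd_pct_change`, `dz`, `alpha`, `power`, `n_required`,
#'   `achieved_power`.
#' @examples
#' sample_size_paired(1, 1)$n_required   # 10
#' sample_size_paired(0.5, 1)$n_required # 34
#' @export
sample_size_paired <- function(mean_change, sd_change, alpha = 0.05,
                               power = 0.80, n_max = 1e6) {
  if (!is.numeric(sd_change) || sd_change <= 0)
    stop("'sd_change' must be positive")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  dz <- mean_change / sd_change
  if (dz == 0) stop("zero expected change: no finite sample size")
  # normal-approximation starting point, then exact scan
  n <- max(2, floor(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
                       abs(dz))^2) - 2)
  while (n <= n_max && power_paired(n, abs(dz), alpha) < power) n <- n + 1
  if (n > n_max) stop("required sample size exceeds 'n_max'")
  # the approximation start can overshoot: walk back to the smallest n
  while (n > 2 && power_paired(n - 1, abs(dz), alpha) >= power) n <- n - 1
  structure(list(expected_pct_change = mean_change,
                 sd_pct_change = sd_change, dz = dz, alpha = alpha,
                 power = power, n_required = as.integer(n),
                 achieved_power = power_paired(n, abs(dz), alpha)),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, digits = 3, ...) {
  cat("Paired-t sample size: n =", x$n_required,
      "for", format(x$expected_pct_change, digits = digits),
      "% expected change (SD", format(x$sd_pct_change, digits = digits),
      "%, dz =", format(x$dz, digits = digits),
      "), alpha =", x$alpha, ", power >=", x$power,
      "(achieved", format(x$achieved_power, digits = digits), ")\n")
  invisible(x)
}

#' Sample-size curve over a grid of expected changes
#'
#' [sample_size_paired()] per grid point; the standard 0.5%--10% range of
#' expected change in tracer retention informs longitudinal study designs.
#'
#' @param effects Grid of expected percentage changes (default
#'   `seq(0.5, 10, by = 0.5)`).
#' @param sd_change SD of percentage change (> 0).
#' @param alpha,power As in [sample_size_paired()].
#' @return `data.frame` with columns `expected_pct_change`,
#'   `sd_pct_change`, `alpha`, `power`, `n_required`.
#' @export
sample_size_curve <- function(effects = seq(0.5, 10, by = 0.5), sd_change,
                              alpha = 0.05, power = 0.80) {
  if (length(effects) < 1L || any(effects == 0))
    stop("'effects' must be a grid of non-zero expected changes")
  rows <- lapply(effects, function(e)
    sample_size_paired(e, sd_change, alpha, power))
  data.frame(expected_pct_change = effects,
             sd_pct_change = sd_change, alpha = alpha, power = power,
             n_required = vapply(rows, `[[`, integer(1), "n_required"))
}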