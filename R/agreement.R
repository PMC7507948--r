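# Method-comparison statistics: Bland-Altman limits of agreement, ICC(2,1),
# Lin's concordance correlation.

#' Bland-Altman limits of agreement
#'
#' Differences are taken as d = y - x (test minus reference).  Bias is the
#' mean difference, limits of agreement are bias +/- 1.96 SD(d), and the
#' confidence intervals follow Bland & Altman's 1999 variance forms:
#' bias CI uses SD(d)/sqrt(n), each limit's CI uses
#' SD(d) sqrt(1/n + 1.96^2 / (2(n-1))), both with t(n-1) quantiles.
#'
#' @param x reference series (e.g. invasive FPP, mmHg).
#' @param y test series (e.g. virtual FPP, mmHg), same length, n >= 3.
#' @param alpha two-sided CI level (default 0.05).
#' @return list of class \code{bland_altman}: \code{n}, \code{bias},
#'   \code{sd_diff}, \code{bias_ci}, \code{loa_upper}, \code{loa_lower},
#'   \code{loa_upper_ci}, \code{loa_lower_ci}, \code{alpha}.
#' @examples
#' bland_altman(c(2, 3, 5), c(3, 2, 5))
#' @export
bland_altman <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y))
    pf_stop("'x' and 'y' must have equal length", "pf_parameter_error")
  if (length(x) < 3L)
    pf_stop("need n >= 3 pairs", "pf_parameter_error")
  d <- y - x
  bland_altman_summary(bias = mean(d), sd_diff = stats::sd(d),
                       n = length(d), alpha = alpha)
}

#' @rdname bland_altman
#' @param bias mean difference.
#' @param sd_diff sample SD of the differences (n - 1 denominator).
#' @param n number of pairs.
#' @details \code{bland_altman_summary} computes the same report from
#'   summary statistics, so printed bias/LoA values can be carried through
#'   the CI arithmetic without the raw pairs.
#' @export
bland_altman_summary <- function(bias, sd_diff, n, alpha = 0.05) {
  if (n < 3L) pf_stop("need n >= 3", "pf_parameter_error")
  if (sd_diff < 0) pf_stop("'sd_diff' must be >= 0", "pf_parameter_error")
  z <- 1.96
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  loa_u <- bias + z * sd_diff
  loa_l <- bias - z * sd_diff
  half_bias <- tq * sd_diff / sqrt(n)
  half_loa <- tq * sd_diff * sqrt(1 / n + z^2 / (2 * (n - 1)))
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 bias_ci = c(bias - half_bias, bias + half_bias),
                 loa_upper = loa_u, loa_lower = loa_l,
                 loa_upper_ci = c(loa_u - half_loa, loa_u + half_loa),
                 loa_lower_ci = c(loa_l - half_loa, loa_l + half_loa),
                 alpha = alpha),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  ci <- function(v) sprintf("(%.3f to %.3f)", v[1], v[2])
  cat(sprintf("Bland-Altman agreement, n = %d\n", x$n))
  cat(sprintf("  bias      %8.3f  95%% CI %s\n", x$bias, ci(x$bias_ci)))
  cat(sprintf("  upper LoA %8.3f  95%% CI %s\n", x$loa_upper, ci(x$loa_upper_ci)))
  cat(sprintf("  lower LoA %8.3f  95%% CI %s\n", x$loa_lower, ci(x$loa_lower_ci)))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, computed
#' from the two-way ANOVA mean squares of an n x 2 (subject x method)
#' layout; the confidence interval follows McGraw & Wong's F-distribution
#' bounds.  Absolute agreement is the appropriate form for method
#' comparison: a constant offset between methods lowers the coefficient.
#'
#' @param x,y paired measurements, n >= 3.
#' @param alpha CI level.
#' @return list with \code{icc}, \code{ci}, the mean squares, \code{n}.
#' @export
icc_absolute_agreement <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3L)
    pf_stop("need equal-length series with n >= 3", "pf_parameter_error")
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  if (all(dat == grand))
    pf_stop("zero total variance: ICC undefined", "pf_undefined_error")
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  if (abs(icc - 1) < 1e-12 || mse == 0 && msc == 0) {
    ci <- c(icc, icc)
  } else {
    r <- icc
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(max(-1, lo), min(1, hi))
  }
  list(icc = icc, ci = ci, msr = msr, msc = msc, mse = mse, n = n)
}

#' Lin's concordance correlation coefficient
#'
#' ccc = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2) with 1/n (biased)
#' moments; the CI applies the normal approximation on Fisher's
#' z-transform of the coefficient with Lin's variance.
#'
#' @param x,y paired measurements, n >= 3.
#' @param alpha CI level.
#' @return list with \code{ccc} and \code{ci}.
#' @export
lin_ccc <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3L)
    pf_stop("need equal-length series with n >= 3", "pf_parameter_error")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0 && mx == my)
    pf_stop("zero variance in both series: CCC undefined", "pf_undefined_error")
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)

  if (abs(ccc) >= 1 - 1e-12 || sx2 == 0 || sy2 == 0) {
    ci <- c(ccc, ccc)
  } else {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    zq <- stats::qnorm(1 - alpha / 2)
    ci <- tanh(c(z - zq * sqrt(sz2), z + zq * sqrt(sz2)))
  }
  list(ccc = ccc, ci = ci, n = n)
}

#' Full agreement report
#'
#' Combines \code{\link{bland_altman}}, \code{\link{icc_absolute_agreement}}
#' and \code{\link{lin_ccc}} for a pair of series.
#'
#' @param x reference series; @param y test series; @param alpha CI level.
#' @return object of class \code{agreement_report}.
#' @export
agreement_report <- function(x, y, alpha = 0.05) {
  ba <- bland_altman(x, y, alpha)
  icc <- icc_absolute_agreement(x, y, alpha)
  ccc <- lin_ccc(x, y, alpha)
  structure(c(ba[setdiff(names(ba), "alpha")],
              list(icc = icc$icc, icc_ci = icc$ci,
                   ccc = ccc$ccc, ccc_ci = ccc$ci, alpha = alpha)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  ci <- function(v) sprintf("(%.3f to %.3f)", v[1], v[2])
  cat(sprintf("Agreement report, n = %d\n", x$n))
  cat(sprintf("  bias      %8.3f  95%% CI %s\n", x$bias, ci(x$bias_ci)))
  cat(sprintf("  upper LoA %8.3f  95%% CI %s\n", x$loa_upper, ci(x$loa_upper_ci)))
  cat(sprintf("  lower LoA %8.3f  95%% CI %s\n", x$loa_lower, ci(x$loa_lower_ci)))
  cat(sprintf("  ICC(2,1)  %8.3f  95%% CI %s\n", x$icc, ci(x$icc_ci)))
  cat(sprintf("  Lin CCC   %8.3f  95%% CI %s\n", x$ccc, ci(x$ccc_ci)))
  invisible(x)
}
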