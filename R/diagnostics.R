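# Diagnostic-accuracy statistics: empirical AUC with DeLong CI, exact
# binomial (Clopper-Pearson) intervals, log-method likelihood-ratio CIs,
# and the threshold-based 2x2 report.

#' Empirical ROC area with DeLong interval
#'
#' AUC by the Mann-Whitney pair-counting estimator (ties count one half);
#' the confidence interval uses DeLong's structural-component variance with
#' a normal approximation, truncated to [0, 1].
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @param alpha CI level.
#' @return list with \code{auc}, \code{ci}, \code{n_pos}, \code{n_neg}.
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))  # auc 0.75
#' @export
roc_auc <- function(scores, labels, alpha = 0.05) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    pf_stop("'scores' and 'labels' must have equal length", "pf_parameter_error")
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    pf_stop("both classes must be present", "pf_parameter_error")
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)          # per-positive structural components
  v01 <- colMeans(psi)          # per-negative
  s2 <- if (m > 1) stats::var(v10) / m else 0
  s2 <- s2 + if (n > 1) stats::var(v01) / n else 0
  zq <- stats::qnorm(1 - alpha / 2)
  ci <- c(max(0, auc - zq * sqrt(s2)), min(1, auc + zq * sqrt(s2)))
  list(auc = auc, ci = ci, n_pos = m, n_neg = n)
}

#' Exact binomial proportion interval
#'
#' Clopper-Pearson interval via Beta quantiles; the conventional exact
#' choice for sensitivity/specificity intervals.
#'
#' @param successes,n counts with 0 <= successes <= n, n >= 1.
#' @param alpha CI level.
#' @return c(lower, upper) on the proportion scale.
#' @examples
#' clopper_pearson(12, 13)  # (0.640, 0.998)
#' @export
clopper_pearson <- function(successes, n, alpha = 0.05) {
  if (n < 1L || successes < 0L || successes > n)
    pf_stop("need 0 <= successes <= n, n >= 1", "pf_parameter_error")
  lo <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lo, upper = hi)
}

#' Likelihood-ratio confidence intervals (log method)
#'
#' CI = exp(ln LR +/- z SE) with the delta-method variances
#' SE^2(ln LR+) = (1-se)/(se n_pos) + sp/((1-sp) n_neg) and the analogous
#' form for LR-.  A zero cell makes the ratio undefined; the affected limit
#' is reported as NA with a flag.
#'
#' @param TP,FN,FP,TN confusion counts (row totals >= 1).
#' @param alpha CI level.
#' @return list with \code{lr_pos}, \code{lr_pos_ci}, \code{lr_neg},
#'   \code{lr_neg_ci}, and logical \code{undefined} flags.
#' @examples
#' likelihood_ratio_ci(12, 1, 1, 11)
#' @export
likelihood_ratio_ci <- function(TP, FN, FP, TN, alpha = 0.05) {
  if (any(c(TP, FN, FP, TN) < 0))
    pf_stop("counts must be >= 0", "pf_parameter_error")
  n_pos <- TP + FN; n_neg <- FP + TN
  if (n_pos < 1L || n_neg < 1L)
    pf_stop("row totals must be >= 1", "pf_parameter_error")
  se <- TP / n_pos; sp <- TN / n_neg
  zq <- stats::qnorm(1 - alpha / 2)
  mk <- function(lr, s2) {
    if (!is.finite(lr) || lr == 0 || !is.finite(s2))
      list(lr = lr, ci = c(NA_real_, NA_real_), undefined = TRUE)
    else
      list(lr = lr, ci = exp(log(lr) + c(-1, 1) * zq * sqrt(s2)),
           undefined = FALSE)
  }
  pos <- mk(se / (1 - sp),
            (1 - se) / (se * n_pos) + sp / ((1 - sp) * n_neg))
  neg <- mk((1 - se) / sp,
            se / ((1 - se) * n_pos) + (1 - sp) / (sp * n_neg))
  list(lr_pos = pos$lr, lr_pos_ci = pos$ci, lr_pos_undefined = pos$undefined,
       lr_neg = neg$lr, lr_neg_ci = neg$ci, lr_neg_undefined = neg$undefined)
}

#' Threshold diagnostics for portal hypertension
#'
#' Classifies \code{score > threshold} as a positive call (the operating
#' definition of portal hypertension is an invasive FPP strictly above
#' 12 mmHg) and reports the 2x2 table, sensitivity and specificity as
#' percentages with Clopper-Pearson intervals, likelihood ratios with
#' log-method intervals, and the empirical AUC with its DeLong interval.
#'
#' @param scores test values (virtual FPP, mmHg).
#' @param labels true condition (logical, or 0/1); both classes required.
#' @param threshold decision threshold, mmHg (default 12).
#' @param alpha CI level.
#' @return object of class \code{diagnostic_report}.
#' @export
diagnostic_metrics <- function(scores, labels, threshold = 12, alpha = 0.05) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    pf_stop("both classes must be present", "pf_parameter_error")
  call_pos <- scores > threshold
  TP <- sum(call_pos & labels); FN <- sum(!call_pos & labels)
  FP <- sum(call_pos & !labels); TN <- sum(!call_pos & !labels)
  sens <- TP / (TP + FN); spec <- TN / (TN + FP)
  lr <- likelihood_ratio_ci(TP, FN, FP, TN, alpha)
  roc <- roc_auc(scores, labels, alpha)
  structure(list(threshold = threshold, TP = TP, FN = FN, FP = FP, TN = TN,
                 sensitivity = 100 * sens,
                 sensitivity_ci = 100 * clopper_pearson(TP, TP + FN, alpha),
                 specificity = 100 * spec,
                 specificity_ci = 100 * clopper_pearson(TN, TN + FP, alpha),
                 lr_pos = lr$lr_pos, lr_pos_ci = lr$lr_pos_ci,
                 lr_neg = lr$lr_neg, lr_neg_ci = lr$lr_neg_ci,
                 auc = roc$auc, auc_ci = roc$ci, alpha = alpha),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  ci <- function(v, d = 1) sprintf(paste0("(%.", d, "f to %.", d, "f)"),
                                   v[1], v[2])
  cat(sprintf("Diagnostics at threshold %g mmHg\n", x$threshold))
  cat(sprintf("  2x2: TP %d, FN %d, FP %d, TN %d\n", x$TP, x$FN, x$FP, x$TN))
  cat(sprintf("  sensitivity %.1f%%  95%% CI %s\n", x$sensitivity,
              ci(x$sensitivity_ci)))
  cat(sprintf("  specificity %.1f%%  95%% CI %s\n", x$specificity,
              ci(x$specificity_ci)))
  cat(sprintf("  LR+ %.1f %s   LR- %.2f %s\n", x$lr_pos, ci(x$lr_pos_ci),
              x$lr_neg, ci(x$lr_neg_ci, 2)))
  cat(sprintf("  AUC %.3f  95%% CI %s\n", x$auc, ci(x$auc_ci, 3)))
  invisible(x)
}
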