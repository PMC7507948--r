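# Group summary tables in the study's "M +/- SD" layout with
# pairwise-vs-control significance flags.

#' Per-group summary with significance flags
#'
#' Summarises one quantity per group as mean +/- SD and flags groups that
#' differ from the first (control) group at P < 0.05.  Test selection
#' follows the study's rules: each pairwise comparison uses Student's
#' t-test when both groups pass a Shapiro-Wilk normality check, otherwise
#' the Mann-Whitney U test; an overall ANOVA (or Kruskal-Wallis) P-value
#' across all groups is reported alongside.
#'
#' @param cohort a \code{cohort}, or a numeric vector of values (then
#'   \code{groups} must be given).
#' @param quantity for a cohort: "fpp", "diameter" or "velocity"; the latter
#'   two need \code{vessel}.
#' @param vessel vessel name for diameter/velocity quantities.
#' @param groups grouping factor when \code{cohort} is a numeric vector.
#' @return data frame of class \code{group_table} with columns \code{group},
#'   \code{n}, \code{mean}, \code{sd}, \code{label} ("6.6 ± 1.1" style),
#'   \code{p_vs_control}, \code{flag}; attributes \code{overall_p} and
#'   \code{overall_test}.
#' @export
group_table <- function(cohort, quantity = "fpp", vessel = NULL,
                        groups = NULL) {
  if (inherits(cohort, "cohort")) {
    if (quantity == "fpp") {
      values <- cohort$animals$fpp_true_mmhg
      groups <- cohort$animals$group
    } else {
      col <- switch(quantity, diameter = "d_us_mm", velocity = "vmax_cm_s",
                    pf_stop("quantity must be fpp, diameter or velocity",
                            "pf_parameter_error"))
      if (is.null(vessel))
        pf_stop("'vessel' required for diameter/velocity tables",
                "pf_parameter_error")
      m <- cohort$measurements[cohort$measurements$vessel == vessel, ]
      values <- m[[col]]; groups <- m$group
    }
  } else {
    values <- cohort
    if (is.null(groups)) pf_stop("'groups' required", "pf_parameter_error")
  }
  groups <- factor(groups, levels = unique(groups))
  if (nlevels(groups) < 2L)
    pf_stop("need >= 2 groups", "pf_parameter_error")
  ns <- tapply(values, groups, length)
  if (any(ns < 2L))
    pf_stop("every group needs >= 2 observations", "pf_parameter_error")

  is_normal <- function(v) {
    if (stats::sd(v) == 0) return(TRUE)
    v <- v[seq_len(min(length(v), 5000L))]      # shapiro.test ceiling
    stats::shapiro.test(v)$p.value > 0.05
  }
  norm <- tapply(values, groups, is_normal)
  all_norm <- all(norm)

  overall <- if (all_norm) {
    list(test = "anova",
         p = stats::anova(stats::lm(values ~ groups))[["Pr(>F)"]][1])
  } else {
    list(test = "kruskal_wallis",
         p = stats::kruskal.test(values, groups)$p.value)
  }

  lev <- levels(groups)
  ctrl <- values[groups == lev[1]]
  out <- data.frame(group = lev,
                    n = as.integer(ns[lev]),
                    mean = as.numeric(tapply(values, groups, mean)[lev]),
                    sd = as.numeric(tapply(values, groups, stats::sd)[lev]),
                    p_vs_control = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(lev)[-1]) {
    g <- values[groups == lev[i]]
    p <- if (norm[lev[1]] && norm[lev[i]] &&
             (stats::sd(ctrl) > 0 || stats::sd(g) > 0)) {
      if (identical(ctrl, g)) 1 else stats::t.test(ctrl, g)$p.value
    } else if (stats::sd(c(ctrl, g)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(ctrl, g)$p.value)
    out$p_vs_control[i] <- p
  }
  out$flag <- !is.na(out$p_vs_control) & out$p_vs_control < 0.05
  out$label <- sprintf("%.1f ± %.1f%s", out$mean, out$sd,
                       ifelse(out$flag, "*", ""))
  structure(out, class = c("group_table", "data.frame"),
            overall_p = overall$p, overall_test = overall$test)
}

#' @export
print.group_table <- function(x, ...) {
  cat("Group summary (M ± SD; * P < 0.05 vs control):\n")
  print(data.frame(group = x$group, n = x$n, value = x$label),
        row.names = FALSE)
  cat(sprintf("overall %s P = %.3g\n", attr(x, "overall_test"),
              attr(x, "overall_p")))
  invisible(x)
}
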