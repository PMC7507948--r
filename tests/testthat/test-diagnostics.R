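# ROC/AUC, exact binomial intervals, likelihood-ratio intervals, threshold
# report, and the group summary table.

test_that("AUC equals brute-force pair counting and respects symmetry", {
  r <- roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1.0)
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n, labels, 1.2), 1)    # induces ties
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels))
    expect_equal(roc_auc(-scores, labels)$auc,
                 1 - roc_auc(scores, labels)$auc)
    expect_equal(roc_auc(scores, 1 - labels)$auc,
                 1 - roc_auc(scores, labels)$auc)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "pf_parameter_error")
})

test_that("DeLong interval matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (rep in 1:5) {
    n <- 40
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n, labels)
    got <- roc_auc(scores, labels)
    ref <- pROC::ci.auc(pROC::roc(labels, scores, direction = "<",
                                  levels = c(0, 1), quiet = TRUE),
                        method = "delong")
    expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-12)
    expect_equal(got$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson intervals: printed bounds and edge cases", {
  expect_equal(unname(clopper_pearson(12, 13)), c(0.640, 0.998),
               tolerance = 5e-4)
  expect_equal(unname(clopper_pearson(11, 12)), c(0.615, 0.998),
               tolerance = 5e-4)
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson(5, 4), class = "pf_parameter_error")
})

test_that("likelihood-ratio log-method intervals and degenerate tables", {
  lr <- likelihood_ratio_ci(12, 1, 1, 11)
  expect_equal(lr$lr_pos, (12 / 13) / (1 / 12), tolerance = 1e-12)
  expect_equal(lr$lr_pos_ci, c(1.7, 72.8), tolerance = 0.01)
  expect_equal(lr$lr_neg, (1 / 13) / (11 / 12), tolerance = 1e-12)
  expect_equal(round(lr$lr_neg_ci, 2), c(0.01, 0.56))

  sym <- likelihood_ratio_ci(4, 4, 4, 4)
  expect_equal(sym$lr_pos, 1); expect_equal(sym$lr_neg, 1)
  expect_true(sym$lr_pos_ci[1] < 1 && 1 < sym$lr_pos_ci[2])
  expect_true(sym$lr_neg_ci[1] < 1 && 1 < sym$lr_neg_ci[2])

  und <- likelihood_ratio_ci(5, 0, 0, 5)    # perfect separation
  expect_true(und$lr_pos_undefined || !is.finite(und$lr_pos))
  expect_equal(und$lr_neg, 0)
})

test_that("threshold diagnostics build the 2x2 and composite report", {
  # scores realising the table TP 12, FN 1, FP 1, TN 11 at threshold 12
  scores <- c(rep(15, 12), 11, 14, rep(9, 11))
  labels <- c(rep(TRUE, 13), rep(FALSE, 12))
  d <- diagnostic_metrics(scores, labels, threshold = 12)
  expect_equal(c(d$TP, d$FN, d$FP, d$TN), c(12L, 1L, 1L, 11L))
  expect_equal(d$sensitivity, 100 * 12 / 13)
  expect_equal(d$specificity, 100 * 11 / 12)
  expect_equal(round(d$lr_pos, 1), 11.1)
  expect_equal(round(d$lr_neg, 2), 0.08)

  # positivity is strict: a score exactly at threshold is negative
  d2 <- diagnostic_metrics(c(12, 13), c(FALSE, TRUE), threshold = 12)
  expect_equal(c(d2$TP, d2$TN), c(1L, 1L))

  sep <- diagnostic_metrics(c(20, 21, 5, 6), c(1, 1, 0, 0), threshold = 12)
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)
  expect_equal(sep$lr_neg, 0)

  hi <- diagnostic_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1), threshold = 100)
  expect_equal(hi$sensitivity, 0)
  expect_error(diagnostic_metrics(1:4, rep(TRUE, 4)),
               class = "pf_parameter_error")
})

test_that("group tables flag separated groups and format M +/- SD", {
  set.seed(3)
  g <- rep(c("Control", "Treated"), each = 40)
  same <- c(rnorm(40, 10, 1), rnorm(40, 10, 1))
  t1 <- group_table(same, groups = g)
  expect_false(t1$flag[2])

  apart <- c(rnorm(1000, 6.6, 1.1), rnorm(1000, 19.2, 1.9))
  t2 <- group_table(c(apart), groups = rep(c("Control", "CCl4_4mo"),
                                           each = 1000))
  expect_true(t2$flag[2])
  expect_match(t2$label[1], "^\\d+\\.\\d ± \\d+\\.\\d$")

  coh <- generate_cohort(n_per_group = 30, seed = 15)
  t3 <- group_table(coh, "fpp")
  expect_equal(t3$group[1], "Control")
  expect_true(all(t3$flag[-1]))          # every dosed group separates
  t4 <- group_table(coh, "diameter", vessel = "portal_vein")
  expect_true(all(t4$flag[-1]))
  expect_error(group_table(coh$animals$fpp_true_mmhg,
                           groups = rep("g1", nrow(coh$animals))),
               class = "pf_parameter_error")
})
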