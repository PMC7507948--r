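# Bland-Altman, ICC(2,1) and Lin's CCC against hand computations,
# independent ANOVA decomposition, and interval-coverage simulation.

test_that("Bland-Altman hand example and internal consistency", {
  expect_error(bland_altman(1:2, 1:2), class = "pf_parameter_error")
  expect_error(bland_altman(1:4, 1:5), class = "pf_parameter_error")

  ba0 <- bland_altman(c(3, 7, 9, 4), c(3, 7, 9, 4))
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$loa_upper, 0); expect_equal(ba0$loa_lower, 0)

  ba <- bland_altman(c(2, 3, 5), c(3, 2, 5))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_upper, 1.96)
  expect_equal(ba$loa_lower, -1.96)

  set.seed(5)
  x <- rnorm(30, 10, 3); y <- x + rnorm(30, 0.5, 1)
  b <- bland_altman(x, y)
  expect_equal(b$loa_upper - b$loa_lower, 2 * 1.96 * b$sd_diff)
  expect_equal((b$loa_upper + b$loa_lower) / 2, b$bias)
  expect_true(b$bias_ci[1] < b$bias && b$bias < b$bias_ci[2])
  expect_true(b$loa_upper_ci[1] < b$loa_upper &&
                b$loa_upper < b$loa_upper_ci[2])
})

test_that("summary-statistic entry reproduces the full CI arithmetic", {
  b1 <- bland_altman_summary(bias = -0.22, sd_diff = 1.2551, n = 25)
  b2 <- {
    set.seed(1)
    d <- rnorm(25)
    d <- (d - mean(d)) / sd(d) * 1.2551 - 0.22    # exact moments
    bland_altman(rep(0, 25), d)
  }
  expect_equal(b1$bias, b2$bias, tolerance = 1e-12)
  expect_equal(b1$bias_ci, b2$bias_ci, tolerance = 1e-10)
  expect_equal(b1$loa_upper_ci, b2$loa_upper_ci, tolerance = 1e-10)
})

test_that("ICC(2,1) equals a from-first-principles ANOVA decomposition", {
  expect_equal(icc_absolute_agreement(c(1, 2, 3), c(1, 2, 3))$icc, 1)
  # a large constant shift collapses absolute agreement below Pearson r = 1
  sh <- icc_absolute_agreement(c(1, 2, 3, 4), c(11, 12, 13, 14))
  expect_lt(sh$icc, 0.1)

  set.seed(33)
  for (rep in 1:5) {
    x <- rnorm(10, 12, 4); y <- x + rnorm(10, 0.3, 1.2)
    got <- icc_absolute_agreement(x, y)
    # independent oracle: two-way ANOVA via stats::aov
    long <- data.frame(v = c(x, y),
                       subj = factor(rep(1:10, 2)),
                       meth = factor(rep(1:2, each = 10)))
    ms <- summary(stats::aov(v ~ subj + meth, data = long))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    n <- 10; k <- 2
    icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    expect_equal(got$icc, icc_oracle, tolerance = 1e-10)
    expect_true(got$ci[1] <= got$icc && got$icc <= got$ci[2])
  }
  expect_error(icc_absolute_agreement(rep(1, 5), rep(1, 5)),
               class = "pf_undefined_error")
})

test_that("Lin's CCC: hand moments, identity, and |CCC| <= |r|", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3))$ccc, 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7, tolerance = 1e-12)
  set.seed(14)
  for (rep in 1:20) {
    x <- rnorm(15); y <- 0.6 * x + rnorm(15, 0.4, 0.8)
    cc <- lin_ccc(x, y)
    expect_lte(abs(cc$ccc), abs(cor(x, y)) + 1e-12)
    expect_true(cc$ci[1] <= cc$ccc && cc$ccc <= cc$ci[2])
  }
  expect_error(lin_ccc(rep(2, 4), rep(2, 4)), class = "pf_undefined_error")
})

test_that("interval procedures achieve nominal coverage under their models", {
  set.seed(99)
  nrep <- 400
  mu_d <- 0.4; sd_d <- 1.3; n <- 25
  hit_bias <- hit_loa <- logical(nrep)
  true_loa <- mu_d + 1.96 * sd_d
  for (i in seq_len(nrep)) {
    d <- rnorm(n, mu_d, sd_d)
    b <- bland_altman_summary(mean(d), sd(d), n)
    hit_bias[i] <- b$bias_ci[1] <= mu_d && mu_d <= b$bias_ci[2]
    hit_loa[i] <- b$loa_upper_ci[1] <= true_loa &&
      true_loa <= b$loa_upper_ci[2]
  }
  mc3 <- 3 * sqrt(0.95 * 0.05 / nrep)
  expect_gt(mean(hit_bias), 0.95 - mc3)   # exact t interval
  expect_lt(mean(hit_bias), 0.95 + mc3)
  expect_gt(mean(hit_loa), 0.95 - mc3)    # 1999 approximate LoA interval

  # Clopper-Pearson is conservative: coverage >= nominal
  p0 <- 0.85; nb <- 20
  hit_cp <- vapply(seq_len(nrep), function(i) {
    ci <- clopper_pearson(rbinom(1, nb, p0), nb)
    ci[1] <= p0 && p0 <= ci[2]
  }, TRUE)
  expect_gte(mean(hit_cp), 0.95 - mc3)
})
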