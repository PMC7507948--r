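# Synthetic cohort generator: defaults, determinism, calibration,
# forward-consistent truth, measurement noise, density protocol.

test_that("default group parameters carry the study's printed moments", {
  p <- default_group_params()
  expect_length(p, 5L)
  expect_equal(unname(p[[1]]$fpp), c(6.6, 1.1))            # control FPP
  expect_equal(unname(p[[5]]$fpp), c(19.2, 1.9))           # 4-month FPP
  expect_equal(unname(p[[5]]$diameter["portal_vein", ]), c(9.5, 1.3))
  expect_equal(unname(p[[5]]$velocity["portal_vein", ]), c(22.0, 1.6))
  expect_equal(unname(p[[1]]$velocity["splenic", ]), c(16.5, 2.3))
  expect_equal(unname(p[[3]]$diameter["inferior_mesenteric", ]), c(2.9, 0.3))
  expect_equal(unname(p[[1]]$rho), c(1050, 15))
  expect_equal(unname(p[[1]]$mu), c(3.5e-3, 0.3e-3))
})

test_that("cohorts are a pure function of (params, n, seed, mode)", {
  a <- generate_cohort(n_per_group = 3, seed = 42)
  b <- generate_cohort(n_per_group = 3, seed = 42)
  expect_identical(a, b)
  c2 <- generate_cohort(n_per_group = 3, seed = 43)
  expect_false(identical(a$measurements$d_mm, c2$measurements$d_mm))

  # adding animals must not perturb earlier draws
  big <- generate_cohort(n_per_group = 5, seed = 42)
  first_group_ids <- a$animals$animal_id[1:3]
  expect_identical(
    a$measurements[a$measurements$animal_id %in% first_group_ids, ],
    big$measurements[big$measurements$animal_id %in% first_group_ids, ])
})

test_that("zero SDs collapse every animal onto its group mean", {
  p <- default_group_params()
  p <- lapply(p, function(g) {
    g$fpp["sd"] <- 0; g$rho["sd"] <- 0; g$mu["sd"] <- 0
    g$diameter[, "sd"] <- 0; g$velocity[, "sd"] <- 0
    g
  })
  coh <- generate_cohort(p, n_per_group = 3, seed = 9)
  for (i in seq_along(p)) {
    g <- p[[i]]$group
    expect_true(all(coh$animals$fpp_true_mmhg[coh$animals$group == g] ==
                      p[[i]]$fpp["mean"]))
    m <- coh$measurements[coh$measurements$group == g, ]
    expect_equal(m$d_mm,
                 rep(unname(p[[i]]$diameter[, "mean"]), 3), tolerance = 0)
  }
  expect_error(generate_cohort(list(), 2, 1), class = "pf_config_error")
})

test_that("moderate-n sampling tracks configured group moments", {
  coh <- generate_cohort(n_per_group = 2000, seed = 4)
  # benign (low-CV) cells: mean within 3 SE, SD within 3 SE
  fpp <- coh$animals$fpp_true_mmhg[coh$animals$group == "Control"]
  expect_lt(abs(mean(fpp) - 6.6), 3 * 1.1 / sqrt(2000))
  expect_lt(abs(sd(fpp) - 1.1), 3 * 1.1 / sqrt(2 * 1999))
  d <- coh$measurements
  pv4 <- d$d_mm[d$group == "CCl4_4mo" & d$vessel == "portal_vein"]
  expect_lt(abs(mean(pv4) - 9.5), 3 * 1.3 / sqrt(2000))
})

test_that("forward-consistent truth is exactly recovered by the pipeline", {
  coh <- generate_cohort(n_per_group = 2, seed = 31,
                         mode = "forward_consistent")
  for (id in coh$animals$animal_id) {
    rec <- get_animal(coh, id)
    fit <- vfpp(rec)
    expect_identical(fit$vfpp_mmhg, rec$fpp_true_mmhg)
    expect_gt(rec$fpp_true_mmhg, rec$p_ref_mmhg)  # viscous rise is positive
  }
})

test_that("forward truth is linear in viscosity above the reference", {
  coh <- generate_cohort(n_per_group = 1, seed = 8,
                         mode = "forward_consistent")
  rec <- get_animal(coh, coh$animals$animal_id[1])
  f1 <- forward_truth(rec, p_ref = 0)
  rec2 <- rec; rec2$blood$mu <- 2 * rec$blood$mu
  f2 <- forward_truth(rec2, p_ref = 0)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  # p_ref enters additively
  expect_equal(forward_truth(rec, p_ref = 5) - f1, 5, tolerance = 1e-12)
})

test_that("blood-density protocol: exactness, floor, and SE of the mean", {
  expect_equal(simulate_blood_density(1050, 5, noise_sd = 0), 1050)
  expect_error(simulate_blood_density(1050, 2, 5),
               class = "pf_parameter_error")
  reps <- vapply(1:3000, function(s)
    simulate_blood_density(1050, n_repeats = 4, noise_sd = 8, seed = s), 0)
  expect_equal(var(reps), 8^2 / 4, tolerance = 0.12)
})

test_that("Doppler noise has the configured CV, determinism, and a no-op at 0", {
  coh <- generate_cohort(n_per_group = 1, seed = 13)
  rec <- get_animal(coh, coh$animals$animal_id[1])
  expect_identical(add_doppler_noise(rec, 0, 0, seed = 1)$vessels,
                   rec$vessels)
  expect_identical(add_doppler_noise(rec, 0.05, 0.05, seed = 7),
                   add_doppler_noise(rec, 0.05, 0.05, seed = 7))
  ratios <- unlist(lapply(1:600, function(s) {
    add_doppler_noise(rec, 0.05, 0, seed = s)$vessels$d_us_mm /
      rec$vessels$d_us_mm
  }))
  expect_equal(sd(ratios), 0.05, tolerance = 0.03)
  expect_equal(mean(ratios), 1, tolerance = 0.003)
  # geometry is untouched
  expect_identical(add_doppler_noise(rec, 0.1, 0.1, seed = 2)$vessels$d_mm,
                   rec$vessels$d_mm)
})

test_that("cohort serialises to CSV and JSON", {
  coh <- generate_cohort(n_per_group = 2, seed = 6)
  p <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 10L * 6L)
  expect_setequal(names(df), c("animal_id", "group", "vessel", "d_us_mm",
                               "vmax_cm_s", "rho", "mu", "fpp_true_mmHg"))
  pj <- tempfile(fileext = ".json")
  write_cohort_json(coh, pj)
  j <- jsonlite::fromJSON(pj, simplifyDataFrame = FALSE)
  expect_length(j, 10L)
  expect_equal(j[[1]]$animal_id, coh$animals$animal_id[1])
})
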