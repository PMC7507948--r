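# Network solver against closed-form Poiseuille oracles and its physical
# invariants: mass conservation, linearity, symmetry, monotonicity.

test_that("segment resistance matches the uniform limit and quadrature", {
  mu <- 3.5e-3
  # uniform tube limit
  expect_equal(segment_resistance(4.5, 4.5, 50, mu),
               128 * mu * 0.05 / (pi * 0.0045^4), tolerance = 1e-14)
  # independent quadrature oracle for the linear taper (midpoint rule)
  quad_R <- function(d0, d1, L, mu, n = 1e4) {
    x <- (seq_len(n) - 0.5) / n
    d <- (d0 + (d1 - d0) * x) / 1000
    sum(128 * mu / (pi * d^4)) * (L / 1000) / n
  }
  for (dd in list(c(4, 6), c(2, 9), c(7, 3))) {
    expect_equal(segment_resistance(dd[1], dd[2], 33, mu),
                 quad_R(dd[1], dd[2], 33, mu, n = 2e5), tolerance = 1e-8)
  }
  expect_error(segment_resistance(0, 4, 10, mu), class = "pf_parameter_error")
})

test_that("poiseuille_drop obeys the d^-4 law and its hand value", {
  mu <- 3.5e-3
  expect_equal(poiseuille_drop(4.5, 50, mu, 0), 0)
  # direct formula evaluation frozen as the oracle value
  expect_equal(poiseuille_drop(4.5, 50, mu, 3.763e-6),
               128 * mu * 0.05 * 3.763e-6 / (pi * 0.0045^4),
               tolerance = 1e-14)
  expect_equal(poiseuille_drop(4.5, 50, mu, 3.763e-6), 65.43, tolerance = 1e-3)
  expect_equal(poiseuille_drop(2, 50, mu, 1e-6) / poiseuille_drop(4, 50, mu, 1e-6),
               16, tolerance = 1e-12)
})

test_that("Reynolds number confirms the laminar regime at canine scale", {
  re <- reynolds(4.5, 23.66, 1050, 3.5e-3)
  expect_equal(re, 1050 * 0.2366 * 0.0045 / 3.5e-3, tolerance = 1e-12)
  expect_equal(re, 319, tolerance = 0.005)
  expect_lt(reynolds(4.5, 1e-9, 1050, 3.5e-3), 1e-6)   # Re -> 0 with v
  expect_equal(reynolds(4.5, 20, 1050, 7e-3),
               reynolds(4.5, 20, 1050, 3.5e-3) / 2)
})

test_that("single-tube network equals R * Q exactly (straight and tapered)", {
  mu <- 3.5e-3; Q <- 3.763e-6
  for (dd in list(c(4.5, 4.5), c(4, 6), c(6, 4))) {
    tr <- single_tube_tree(d_prox = dd[1], d_dist = dd[2], L = 50)
    bcs <- make_bcs(tr, c(f_in = Q))
    sol <- solve_network(tr, bcs, canine_blood(mu))
    R <- segment_resistance(dd[1], dd[2], 50, mu)
    expect_equal(sol$pressures_pa[["a"]], R * Q, tolerance = 1e-10)
    expect_equal(sol$flows_m3_s[["s1"]], Q, tolerance = 1e-12)
  }
})

test_that("junction continuity holds on random networks", {
  for (s in 1:100) {
    net <- random_network(seed = 1000 + s, max_seg = 50)
    # random flows need not stay in the laminar band; regime warnings are
    # irrelevant to the continuity check
    sol <- suppressWarnings(solve_network(net$tree, net$bcs, canine_blood()))
    expect_lt(sol$residual_rel, 1e-10)
  }
})

test_that("solution is linear in viscosity and in boundary flows", {
  net <- random_network(seed = 77, max_seg = 20)
  s1 <- solve_network(net$tree, net$bcs, canine_blood(mu = 3.5e-3))
  s2 <- solve_network(net$tree, net$bcs, canine_blood(mu = 7.0e-3))
  expect_equal(2 * as.numeric(s1$pressures_pa), as.numeric(s2$pressures_pa),
               tolerance = 1e-10)

  bcs3 <- net$bcs
  vel <- bcs3$kind == "velocity_inlet"
  bcs3$q_m3_s[vel] <- 3 * bcs3$q_m3_s[vel]
  bcs3$v_b_m_s[vel] <- 3 * bcs3$v_b_m_s[vel]
  s3 <- solve_network(net$tree, bcs3, canine_blood(mu = 3.5e-3))
  expect_equal(3 * as.numeric(s1$pressures_pa), as.numeric(s3$pressures_pa),
               tolerance = 1e-10)
})

test_that("symmetric Y gives equal inlet pressures; solves are deterministic", {
  tr <- y_tree()
  bcs <- make_bcs(tr, c(fL = 2e-6, fR = 2e-6))
  sol <- solve_network(tr, bcs, canine_blood())
  expect_identical(sol$pressures_pa[["inL"]], sol$pressures_pa[["inR"]])
  sol2 <- solve_network(tr, bcs, canine_blood())
  expect_identical(sol$pressures_pa, sol2$pressures_pa)
})

test_that("widening any vessel never raises the trunk gauge pressure", {
  coh <- generate_cohort(n_per_group = 1, seed = 21)
  rec <- get_animal(coh, coh$animals$animal_id[1])
  base <- vfpp(rec, config = solver_config(p_ref = 0))
  for (v in rec$vessels$vessel) {
    rec2 <- rec
    i <- rec2$vessels$vessel == v
    rec2$vessels$d_mm[i] <- rec2$vessels$d_mm[i] * 1.3
    rec2$vessels$d_us_mm[i] <- rec2$vessels$d_us_mm[i] * 1.3
    # widen geometry only: keep the same boundary flows by fixing d_us to
    # the original measurement (Q depends on d_us, not d_b)
    rec2$vessels$d_us_mm[i] <- rec$vessels$d_us_mm[i]
    wid <- vfpp(rec2, config = solver_config(p_ref = 0))
    expect_lte(wid$vfpp_mmhg, base$vfpp_mmhg + 1e-12)
  }
})

test_that("solver guards: unreconciled input, missing reference, conversions", {
  tr <- single_tube_tree()
  raw <- make_bcs(tr, c(f_in = 1e-6))
  attr(raw, "reconciled") <- FALSE
  expect_error(solve_network(tr, raw, canine_blood()),
               class = "pf_precondition_error")

  expect_equal(pa_to_mmhg(133.322), 1.0)
  expect_equal(pa_to_mmhg(0), 0)
  expect_equal(pa_to_mmhg(65.5), 0.491, tolerance = 1e-3)
  expect_equal(mmhg_to_pa(pa_to_mmhg(42)), 42)
})

test_that("vFPP is the trunk midpoint plus the absolute reference", {
  mu <- 3.5e-3; Q <- 3.763e-6
  tr <- single_tube_tree(d_prox = 4.5, L = 50)
  sol <- solve_network(tr, make_bcs(tr, c(f_in = Q)), canine_blood(mu))
  drop <- segment_resistance(4.5, 4.5, 50, mu) * Q
  v0 <- extract_vfpp(sol, tr, solver_config(p_ref = 0))
  expect_equal(v0, pa_to_mmhg(drop / 2), tolerance = 1e-12)
  v6 <- extract_vfpp(sol, tr, solver_config(p_ref = 6.6))
  expect_equal(v6 - v0, 6.6)

  tr2 <- single_tube_tree(name = "other")
  sol2 <- solve_network(tr2, make_bcs(tr2, c(f_in = Q)), canine_blood(mu))
  expect_error(extract_vfpp(sol2, tr2), class = "pf_config_error")
})

test_that("flow solution exports CSV and VTK", {
  tr <- canonical_tree()
  coh <- generate_cohort(n_per_group = 1, seed = 2)
  fit <- vfpp(get_animal(coh, coh$animals$animal_id[1]))
  p1 <- tempfile(fileext = ".csv")
  write_flow_csv(fit$solution, fit$tree, p1)
  df <- read.csv(p1)
  expect_equal(sum(df$record == "node"), 7L)
  expect_equal(sum(df$record == "segment"), 6L)
  p2 <- tempfile(fileext = ".vtk")
  write_flow_vtk(fit$solution, fit$tree, p2)
  expect_true(any(grepl("SCALARS pressure_Pa", readLines(p2))))
})
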