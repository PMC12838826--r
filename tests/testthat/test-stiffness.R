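test_that("contact-law forward and inverse round-trip exactly", {
  expect_equal(hertz_modulus(2, 1, 0.5, 0), 2)
  expect_equal(hertz_modulus(1, 3.75e-3, 10e-3, 0.5), 10e3, tolerance = 1e-12)
  expect_equal(hertz_deformation(1, 10e3, 10e-3, 0.5), 3.75e-3, tolerance = 1e-12)
  expect_equal(hertz_modulus(4, 1, 0.5, 0), 2 * hertz_modulus(2, 1, 0.5, 0))
  expect_equal(hertz_deformation(0, 10e3, 10e-3), 0)
  expect_error(hertz_modulus(1, 0, 0.01), "invalid deformation")

  set.seed(1)
  for (i in 1:20) {
    P <- stats::runif(1, 0.1, 50)
    E <- stats::runif(1, 1e3, 1e6)
    a <- stats::runif(1, 1e-3, 5e-2)
    nu <- stats::runif(1, 0, 0.5)
    expect_equal(hertz_modulus(P, hertz_deformation(P, E, a, nu), a, nu), E,
                 tolerance = 1e-12)
  }
})

test_that("ToF-deformation conversion is the exact round-trip relation", {
  expect_equal(tof_to_deformation(0, 1540), 0)
  expect_equal(tof_to_deformation(3.9e-6, 1540), 1540 * 3.9e-6 / 2,
               tolerance = 1e-12) # ~3.003 mm
  expect_equal(deformation_to_tof(tof_to_deformation(2.5e-6, 1540), 1540),
               2.5e-6, tolerance = 1e-15)
  expect_error(tof_to_deformation(-1e-6, 1540), "sign convention")
})

test_that("modulus recovery from a simulated sweep hits the generating value", {
  ind <- std_indenter()
  loads <- force_steps(seq(0, 2, by = 0.25))
  ph <- std_phantom(E = 10e3, h = 40e-3)
  sw <- simulate_sweep(ph, ind, loads)
  tt <- tof_table(sw, forces_N = seq(0, 2, by = 0.25))
  est <- estimate_modulus_from_sweep(tt, v = 1540, ind = ind)
  expect_equal(est$youngs_modulus_E, 10e3, tolerance = 0.01)
  expect_gt(est$fit$r_squared, 0.999)

  allzero <- data.frame(force_N = c(1, 2), tau_s = c(0, 0))
  expect_error(estimate_modulus_from_sweep(allzero, 1540, ind), "degenerate")
  expect_error(estimate_modulus_from_sweep(
    data.frame(force_N = c(0, 1), tau_s = c(0, 1e-6)), 1540, ind), "nonzero")
})

test_that("calibration fits are ordinary least squares with sane degenerate cases", {
  f <- fit_tof_vs_load(c(0, 1, 2, 3), c(1, 3, 5, 7) * 1e-6)
  expect_equal(f$slope, 2e-6, tolerance = 1e-12)
  expect_equal(f$intercept, 1e-6, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  two <- fit_tof_vs_load(c(1, 2), c(5e-6, 3e-6))
  expect_equal(two$r_squared, 1)
  expect_equal(two$slope, -2e-6, tolerance = 1e-12)

  const <- fit_tof_vs_hardness(c(0, 10, 20), rep(2e-6, 3))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)

  # permutation invariance
  x <- c(0, 10, 30, 60); y <- c(7, 3, 2, 1) * 1e-6
  p <- sample(4)
  f1 <- fit_tof_vs_hardness(x, y)
  f2 <- fit_tof_vs_hardness(x[p], y[p])
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$r_squared, f2$r_squared)
})

test_that("simulated hardness series yields a negative tau-vs-hardness slope", {
  ind <- std_indenter()
  HA <- seq(0, 60, by = 10)
  taus <- vapply(seq_along(HA), function(i) {
    ph <- tissue_phantom(10e-3, 1000, shore_to_young(HA[i]))
    sw <- simulate_sweep(ph, ind, force_steps(c(0, 15)), snr_db = 30,
                         seed = 100 + i)
    tof_table(sw, c(0, 15))$tau_s[2]
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_lt(fit_tof_vs_hardness(HA, taus)$slope, 0)
})

test_that("stiffness ranking orders by ascending tau and groups ties", {
  rk <- rank_stiffness(c(beef = 1.0e-6, pork = 2.0e-6, fat = 3.0e-6))
  expect_equal(rk$labels, c("beef", "pork", "fat"))
  expect_equal(rank_stiffness(c(only = 1e-6))$labels, "only")
  tied <- rank_stiffness(c(a = 1e-6, b = 1e-6, c = 2e-6))
  expect_length(tied$groups, 2)
  expect_setequal(tied$groups[[1]], c("a", "b"))
  expect_error(rank_stiffness(c(1, 2)), "named")
})

test_that("pipeline-estimated taus rank phantoms in true modulus order", {
  ind <- std_indenter()
  Es <- c(soft = 12e3, mid = 25e3, stiff = 50e3) # >= 1.5x separation
  tau_at <- function(E, seed, snr) {
    ph <- std_phantom(E = E, beta = 3)
    sw <- simulate_sweep(ph, ind, force_steps(c(0, 5)), snr_db = snr,
                         seed = seed)
    tof_table(sw, c(0, 5))$tau_s[2]
  }
  for (snr in list(NULL, 25)) {
    taus <- vapply(seq_along(Es), function(i) tau_at(Es[i], 200 + i, snr),
                   numeric(1))
    names(taus) <- names(Es)
    expect_equal(rank_stiffness(taus)$labels, c("stiff", "mid", "soft"))
  }
})

test_that("sensitivity curve rates are first differences and detect concavity", {
  cur <- sensitivity_curve(1:5, c(0, 2, 4, 6, 8) * 1e-6)
  expect_equal(unname(cur$rate_of_change), rep(2e-6, 4))

  concave <- sensitivity_curve(1:6, cumsum(c(0, 5, 4, 3, 2, 1)) * 1e-7)
  expect_true(all(diff(concave$rate_of_change) < 0))

  two <- sensitivity_curve(c(1, 3), c(0, 4e-6))
  expect_equal(unname(two$rate_of_change), 2e-6)

  expect_error(sensitivity_curve(c(1, 1, 2), c(0, 1, 2)), "increasing")
  expect_error(sensitivity_curve(1:3, c(1e-6, 2e-6, 3e-6)), "baseline")
})

test_that("operating pressure sits at the knee before the plateau", {
  # steep incoming rates through the 5 kPa level, then a >= 4x drop
  knee <- sensitivity_curve(1:7, cumsum(c(0, 1.0, 0.9, 0.8, 0.7, 0.1, 0.05)) * 1e-6)
  expect_equal(select_operating_pressure(knee), 5)

  flat <- sensitivity_curve(1:5, c(0, 1, 2, 3, 4) * 1e-6)
  expect_equal(select_operating_pressure(flat), 5)

  rising <- sensitivity_curve(1:5, c(0, 1, 3, 6, 10) * 1e-6)
  expect_equal(select_operating_pressure(rising), 5)

  none <- sensitivity_curve(1:4, c(0, 0, 0, 0))
  expect_error(select_operating_pressure(none), "no sensitivity")
})

test_that("strain stiffening propagates to non-increasing sensitivity rates", {
  ind <- std_indenter()
  ph <- tissue_phantom(40e-3, 1540, 15e3, stiffening_beta = 4)
  loads <- pressure_steps(1:7)
  sw <- simulate_sweep(ph, ind, loads, snr_db = 30, seed = 9)
  tt <- tof_table(sw)
  cur <- sensitivity_curve(1:7, tt$tau_s)
  expect_true(all(diff(cur$rate_of_change) <= 1e-9))
})
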