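test_that("voltage scaling follows the symmetric-barrier Boltzmann factor", {
  # zero charge or zero voltage leave the rate untouched
  expect_equal(voltage_scaled_rate(10, 0, -0.09), 10)
  expect_equal(voltage_scaled_rate(10, 1, 0), 10)
  # direct evaluation at -60 mV, T = 293 K: exp(1.1882) ~ 3.281
  expect_equal(voltage_scaled_rate(10, 1, -0.06), 32.81294, tolerance = 1e-6)
  # forward x reverse scaling factors multiply to 1 at every voltage
  for (V in c(-0.12, -0.03, 0.07)) {
    for (zQ in c(-0.7, 0.4, 2)) {
      prod <- voltage_scaled_rate(1, zQ, V, direction = "fwd") *
        voltage_scaled_rate(1, zQ, V, direction = "rev")
      expect_equal(prod, 1, tolerance = 1e-12)
    }
  }
  expect_error(voltage_scaled_rate(NaN, 1, 0), "non-finite")
  expect_error(voltage_scaled_rate(-1, 1, 0), "non-negative")
})

test_that("generator columns sum to zero and ligand coupling is pseudo-first-order", {
  Q <- build_generator(two_state_scheme(2, 1), ion_conditions(), 0)
  expect_equal(colSums(Q), c(A = 0, B = 0), tolerance = 1e-14)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))

  # binding edge 1e6 M^-1 s^-1 at 30 uM external substrate -> 30 s^-1
  s <- binding_scheme(kon = 1e6, koff = 5)
  cond <- ion_conditions(outside = c(S = 30e-6))
  Q <- build_generator(s, cond, 0)
  expect_equal(Q["B", "A"], 30)
  expect_equal(Q["A", "B"], 5)

  # generator columns sum to zero across models, conditions, voltages
  for (m in list(build_dat_model(), build_net_model(), build_sert_model())) {
    for (V in c(-0.09, 0.03)) {
      Q <- build_generator(m$scheme, get_condition_preset("physiological"), V)
      expect_lt(max(abs(colSums(Q))), 1e-9 * max(abs(Q)))
    }
  }

  # coupling to a species unknown to the conditions is a configuration error
  bad <- binding_scheme()
  bad$transitions$lig_f <- "X"
  expect_error(build_generator(bad, cond, 0), "unknown species")
})

test_that("steady state solves the null space and rejects degenerate schemes", {
  p <- steady_state(two_state_scheme(2, 1), ion_conditions(), 0)
  expect_equal(unname(p), c(1, 2) / 3, tolerance = 1e-12)

  # two disjoint components: stationary distribution not unique
  disconnected <- kinetic_scheme(
    states = tibble::tibble(name = c("A", "B", "C", "D"),
                            conformation = rep("outward", 4)),
    transitions = tibble::tibble(from = c("A", "C"), to = c("B", "D"),
                                 kf0 = 1, kr0 = 1, zQ = 0))
  expect_error(steady_state(disconnected, ion_conditions(), 0),
               "not unique")
})

test_that("integration matches the closed-form two-state relaxation", {
  s <- two_state_scheme(2, 1)
  pr <- application_protocol(V = 0)
  tt <- seq(0, 2, by = 0.01)
  traj <- integrate_occupancies(s, ion_conditions(), pr,
                                p0 = c(A = 1, B = 0), t_grid = tt)
  exact <- 1 / 3 + 2 / 3 * exp(-3 * traj$time)
  expect_lt(max(abs(traj$A - exact)), 1e-6)
  # conservation at every time point
  expect_lt(max(abs(traj$A + traj$B - 1)), 1e-6)
})

test_that("long-time integration converges to the algebraic steady state", {
  cond <- get_condition_preset("physiological")
  cond <- set_concentration(cond, "S", "out", 30e-6)
  for (m in list(build_dat_model(), build_sert_model())) {
    # constant conditions: substrate held at 30 uM throughout
    pr <- application_protocol(V = -0.06,
                               segments = list(list(t_start = 0, t_end = 1e4,
                                                    targets = c(S = 30e-6))))
    ss <- steady_state(m$scheme, cond, -0.06)
    traj <- integrate_occupancies(m$scheme, cond, pr,
                                  t_grid = c(0, 10, 100))
    final <- unlist(traj[nrow(traj), m$scheme$states$name])
    expect_lt(max(abs(final - ss)), 1e-5)
  }
})

test_that("occupancy bounds and normalization hold on simulated protocols", {
  m <- build_dat_model()
  traj <- simulate_application(m, 30e-6, -0.06, duration = 2)
  P <- as.matrix(tibble::as_tibble(traj)[, m$scheme$states$name])
  expect_true(all(P >= -1e-9 & P <= 1 + 1e-9))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
})

test_that("application protocols validate segments and relax concentrations", {
  expect_error(application_protocol(0, list(list(t_start = 1, t_end = 0.5,
                                                 targets = c(S = 1e-6)))),
               "exceed")
  expect_error(application_protocol(0, list(
    list(t_start = 0, t_end = 2, targets = c(S = 1e-6)),
    list(t_start = 1, t_end = 3, targets = c(S = 1e-6)))), "overlap")

  # exchange follows a 10 ms exponential: 1 - e^-1 of the target after tau
  pr <- substrate_application(0, conc = 100e-6, t_on = 0.1, duration = 1)
  cond <- ion_conditions()
  ext <- slc6sim:::external_concentrations(pr, cond, c(0.1, 0.11, 0.2))
  expect_equal(unname(ext[1, "S"]), 0)
  expect_equal(unname(ext[2, "S"]), 100e-6 * (1 - exp(-1)),
               tolerance = 1e-10)
  expect_equal(unname(ext[3, "S"]), 100e-6, tolerance = 1e-4)
})
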