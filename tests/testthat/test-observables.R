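# a trajectory with a hand-set occupancy matrix on a simple scheme, for
# closed-form current checks
manual_traj <- function(scheme, cond, V, occ) {
  traj <- tibble::as_tibble(cbind(data.frame(time = seq_len(nrow(occ)) - 1),
                                  occ))
  class(traj) <- c("occupancy_trajectory", class(traj))
  attr(traj, "context") <- list(scheme = scheme, conditions = cond,
                                protocol = application_protocol(V),
                                constants = phys_constants())
  traj
}

test_that("coupled current reproduces the per-edge flux formula", {
  # single edge, p_i = 1, p_j = 0, k = 10 s^-1, zQ = +1, NC = 4e6:
  # I = -F * NC/N_A * 10 = -6.41e-12 A
  s <- two_state_scheme(10, 0, zQ = 1)
  traj <- manual_traj(s, ion_conditions(), 0,
                      data.frame(A = c(1, 1), B = c(0, 0)))
  I <- coupled_current(traj, population_params(4e6))
  expect_equal(I$current[1], -96485 * 4e6 / 6.022e23 * 10, tolerance = 1e-12)
  expect_equal(I$current[1], -6.41e-12, tolerance = 1e-3)

  # at thermodynamic equilibrium every edge flux vanishes
  m <- build_dat_model()
  eq <- equilibrium_conditions()
  ss <- steady_state(m$scheme, eq, 0)
  traj <- integrate_occupancies(m$scheme, eq, application_protocol(0),
                                p0 = ss, t_grid = seq(0, 1, 0.1))
  I <- coupled_current(traj)
  expect_lt(max(abs(I$current)), 1e-18)
})

test_that("uncoupled current is the conducting-state ohmic formula", {
  m <- build_sert_model()
  cond <- get_condition_preset("physiological")
  nm <- m$scheme$states$name
  occ <- matrix(0, 2, length(nm), dimnames = list(NULL, nm))
  occ[, "Tcond"] <- 1e-5
  occ[, "ToCl"] <- 1 - 1e-5
  traj <- manual_traj(m$scheme, cond, -0.06, as.data.frame(occ))
  I <- uncoupled_current(traj, channel_params(2.4e-12, 0.100),
                         population_params(4e6))
  expect_equal(I$current[1], 1e-5 * 2.4e-12 * 4e6 * (-0.16),
               tolerance = 1e-12)
  expect_equal(I$current[1], -1.536e-11, tolerance = 1e-6)

  # V = V_rev: zero driving force regardless of occupancy
  traj2 <- manual_traj(m$scheme, cond, 0.100, as.data.frame(occ))
  expect_true(all(uncoupled_current(traj2)$current == 0))

  # no conducting state in the scheme: identically zero trace
  traj3 <- simulate_application(build_net_model(), 30e-6, -0.06,
                                duration = 1)
  expect_true(all(uncoupled_current(traj3)$current == 0))

  # linearity in driving force and occupancy
  I2 <- uncoupled_current(manual_traj(m$scheme, cond, -0.22,
                                      as.data.frame(2 * occ / 2)),
                          channel_params(), population_params())
  expect_equal(I2$current[1] / I$current[1], (-0.32) / (-0.16),
               tolerance = 1e-12)
})

test_that("total current is the pointwise sum of components", {
  m <- build_dat_model()
  traj <- simulate_application(m, 30e-6, -0.06, duration = 2)
  tot <- total_current(traj)
  expect_equal(tot$current,
               coupled_current(traj)$current +
                 uncoupled_current(traj)$current, tolerance = 1e-15)
})

test_that("uptake flux implements the release-step mass action", {
  # p_bound = 0.5, koff = 30 s^-1, S_in = 0, NC = 4e6 -> 6e7 molecules/s
  s <- binding_scheme(kon = 9e5, koff = 30)
  cond <- ion_conditions(outside = c(S = 30e-6))
  traj <- manual_traj(s, cond, 0, data.frame(A = c(0.5, 0.5),
                                             B = c(0.5, 0.5)))
  up <- substrate_uptake(traj, population_params(4e6))
  expect_equal(up$flux[1], 0.5 * 30 * 4e6, tolerance = 1e-12)
  expect_equal(up$flux[1] / 6.022e23, 9.96e-17, tolerance = 1e-3)

  # intracellular binding equilibrium: S_in = (koff/kon) * p_B/p_A -> 0 flux
  cond_eq <- ion_conditions(outside = c(S = 30e-6),
                            inside = c(S = (30 / 9e5) * (0.5 / 0.5)))
  traj_eq <- manual_traj(s, cond_eq, 0, data.frame(A = 0.5, B = 0.5))
  expect_equal(substrate_uptake(traj_eq)$flux[1], 0, tolerance = 1e-9)

  # S_in = 0: cumulative uptake is monotonically non-decreasing
  m <- build_dat_model()
  traj <- simulate_application(m, 30e-6, -0.06, duration = 2)
  up <- substrate_uptake(traj)
  expect_true(all(diff(up$cumulative) >= -1e-9 * max(up$cumulative)))

  # cumulative trace differentiates back to the flux (uniform fine grid so
  # the central difference is grid-accurate)
  cond30 <- get_condition_preset("physiological")
  prot <- substrate_application(-0.06, 30e-6, t_on = 0.2, duration = 1.5)
  traj_f <- integrate_occupancies(m$scheme, cond30, prot,
                                  t_grid = seq(0, 1.2, by = 0.0005))
  up <- substrate_uptake(traj_f)
  mid <- 2:(nrow(up) - 1)
  num_deriv <- (up$cumulative[mid + 1] - up$cumulative[mid - 1]) /
    (up$time[mid + 1] - up$time[mid - 1])
  sel <- abs(up$flux[mid]) > 0.01 * max(abs(up$flux))
  expect_lt(max(abs(num_deriv[sel] - up$flux[mid][sel]) /
                  max(abs(up$flux))), 1e-3)
})

test_that("amplitude extraction separates peak, plateau and ramp slope", {
  tt <- seq(0, 10, 0.001)
  flat <- tibble::tibble(time = tt, current = 0)
  expect_equal(extract_peak(flat, onset = 1), 0)
  expect_equal(extract_steady(flat, 1, 9), 0)

  # constructed peak (-20 pA at 50 ms) decaying to a -5 pA plateau
  cur <- ifelse(tt < 1, 0, -5e-12 - 15e-12 * exp(-(tt - 1) / 0.03) *
                  (1 - exp(-(tt - 1) / 0.01)) * 3.08)
  peaky <- tibble::tibble(time = tt, current = cur)
  expect_equal(extract_peak(peaky, onset = 1), min(cur), tolerance = 1e-6)
  expect_equal(extract_steady(peaky, 1, 9), -5e-12, tolerance = 1e-3)
  expect_error(extract_peak(peaky, onset = 11), "outside")

  ramp <- tibble::tibble(time = tt, cumulative = 100 * tt)
  expect_equal(extract_uptake_slope(ramp, 0, 10), 100, tolerance = 1e-9)
  zero <- tibble::tibble(time = tt, cumulative = 0 * tt)
  expect_equal(extract_uptake_slope(zero, 0, 10), 0)
  expect_error(extract_uptake_slope(ramp, 0, 1.9), "shorter")

  # ramp + bath artifact: window excludes the artifact edges, slope intact
  art <- bath_artifact(substrate_application(0, 30e-6, t_on = 1,
                                             duration = 8),
                       bath_artifact_params(amplitude = 500), tt)
  noisy_ramp <- tibble::tibble(time = tt,
                               cumulative = 100 * tt + art$fluorescence)
  expect_equal(extract_uptake_slope(noisy_ramp, 1, 9), 100,
               tolerance = 0.01)
})

test_that("DAT currents show a transient peak over a persistent plateau", {
  m <- build_dat_model()
  traj <- simulate_application(m, 30e-6, -0.06, duration = 4)
  cur <- total_current(traj)
  pk <- extract_peak(cur, 0.5)
  st <- extract_steady(cur, 0.5, 4.5)
  expect_lt(pk, 0)           # inward
  expect_lt(st, 0)           # nonzero steady plateau
  expect_gt(abs(pk), abs(st))
})
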