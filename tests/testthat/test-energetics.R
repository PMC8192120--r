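RT <- 8.314 * 293

test_that("step free energies follow -RT log of effective rate ratios", {
  s <- two_state_scheme(5, 5)
  expect_equal(step_delta_g(s, ion_conditions(), 0, "A", "B"), 0)

  s10 <- two_state_scheme(20, 2)
  expect_equal(step_delta_g(s10, ion_conditions(), 0, "A", "B"),
               -RT * log(10), tolerance = 1e-9)
  expect_equal(-RT * log(10), -5608.7, tolerance = 1e-4)

  # halving the concentration of a binding ligand raises dG by RT log 2
  b <- binding_scheme(kon = 1e6, koff = 30)
  c1 <- ion_conditions(outside = c(S = 30e-6))
  c2 <- ion_conditions(outside = c(S = 15e-6))
  expect_equal(step_delta_g(b, c2, 0, "A", "B") -
                 step_delta_g(b, c1, 0, "A", "B"),
               RT * log(2), tolerance = 1e-9)

  # zero-rate direction is flagged, not returned as a number
  c0 <- ion_conditions(outside = c(S = 0))
  expect_error(step_delta_g(b, c0, 0, "A", "B"), "infinite")
})

test_that("closed loops are exactly balanced at equilibrium conditions", {
  eq <- equilibrium_conditions()
  for (m in list(build_dat_model(), build_net_model(), build_sert_model())) {
    for (loop in c("outer", "inner")) {
      path <- model_loop_path(m, loop)
      prof <- loop_profile(m$scheme, eq, 0, path)
      expect_lt(abs(attr(prof, "total")), 1e-9)
      # cumulative column is the prefix sum of the per-step values
      expect_equal(prof$cumulative, cumsum(prof$delta_g), tolerance = 1e-12)
    }
  }
})

test_that("loop totals are path-orientation antisymmetric and rotation invariant", {
  m <- build_dat_model()
  cond <- get_condition_preset("physiological")
  cond <- set_concentration(cond, "S", "out", 30e-6)
  cond <- set_concentration(cond, "S", "in", 30e-6)
  path <- model_loop_path(m, "outer")
  fwd <- attr(loop_profile(m$scheme, cond, -0.06, path), "total")
  rev <- attr(loop_profile(m$scheme, cond, -0.06, rev(path)), "total")
  expect_equal(fwd, -rev, tolerance = 1e-9)

  # starting the loop at a different state leaves the total unchanged
  rot <- c(path[3:(length(path) - 1)], path[1:3])
  expect_equal(attr(loop_profile(m$scheme, cond, -0.06, rot), "total"),
               fwd, tolerance = 1e-9)
  expect_error(loop_profile(m$scheme, cond, 0, c("ToCl", "TiClS")),
               "nonexistent")
})

test_that("voltage shifts loop free energy by sum(zQ) F V exactly", {
  m <- build_sert_model()
  cond <- get_condition_preset("physiological")
  cond <- set_concentration(cond, "S", "out", 30e-6)
  cond <- set_concentration(cond, "S", "in", 30e-6)
  # a trace of external K+ keeps the antiport release step at finite dG
  cond <- set_concentration(cond, "K", "out", 0.005)
  for (loop in c("outer", "inner")) {
    path <- model_loop_path(m, loop)
    p0 <- loop_profile(m$scheme, cond, 0, path)
    pV <- loop_profile(m$scheme, cond, -0.06, path)
    expect_equal(attr(pV, "total") - attr(p0, "total"),
                 attr(pV, "zQ_sum") * 96485 * (-0.06), tolerance = 1e-8)
  }
})

test_that("the DAT outer loop is downhill at 0 and -60 mV under physiological gradients", {
  m <- build_dat_model()
  cond <- get_condition_preset("physiological")
  # substrate present at equal activity on both faces: the loop total then
  # isolates the ionic and electrical driving forces
  cond <- set_concentration(cond, "S", "out", 30e-6)
  cond <- set_concentration(cond, "S", "in", 30e-6)
  path <- model_loop_path(m, "outer")
  g0 <- attr(loop_profile(m$scheme, cond, 0, path), "total")
  g60 <- attr(loop_profile(m$scheme, cond, -0.06, path), "total")
  expect_lt(g0, 0)
  expect_lt(g60, 0)
  # hyperpolarization adds driving for the electrogenic cycle
  expect_lt(g60, g0)
})

test_that("steady state satisfies detailed balance edge-wise at equilibrium", {
  eq <- equilibrium_conditions()
  m <- build_dat_model()
  ss <- steady_state(m$scheme, eq, 0)
  r <- slc6sim:::edge_rates(m$scheme, eq, 0)
  tr <- m$scheme$transitions
  for (e in seq_len(nrow(tr))) {
    fwd <- ss[tr$from[e]] * r$fwd[e]
    rev <- ss[tr$to[e]] * r$rev[e]
    expect_equal(unname(fwd), unname(rev), tolerance = 1e-6 * max(fwd, rev))
  }
})
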