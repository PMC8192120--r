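test_that("all fitters recover generating parameters exactly on noiseless data", {
  x <- c(1, 3, 10, 30, 100, 300, 600) * 1e-6
  h <- fit_hyperbola(x, x / (x + 10e-6))
  expect_rel_equal(h$K_M, 10e-6, 1e-6)
  expect_rel_equal(h$Ymax, 1, 1e-6)

  v <- seq(-0.09, 0.03, by = 0.01)
  yb <- 0.2 + (1 - 0.2) / (1 + exp((-0.03 - v) / 0.025))
  b <- fit_boltzmann(v, yb)
  expect_rel_equal(b$Top, 1, 1e-6)
  expect_rel_equal(b$Bottom, 0.2, 1e-6)
  expect_lt(abs(b$V50 - (-0.03)), 1e-8)
  expect_rel_equal(b$Slope, 0.025, 1e-6)

  l <- fit_line(c(0, 1), c(1, 3))
  expect_equal(l$slope, 2)
  expect_equal(l$intercept, 1)

  t <- seq(0, 3, by = 0.2)
  e <- fit_monoexp(t, 1 - exp(-2 * t))
  expect_rel_equal(e$rate, 2, 1e-8)
})

test_that("hyperbola fit is scale-equivariant and rejects degenerate data", {
  x <- c(2, 5, 20, 60, 200) * 1e-6
  y <- x / (x + 25e-6)
  f1 <- fit_hyperbola(x, y)
  f2 <- fit_hyperbola(x, 2 * y)
  expect_rel_equal(f2$Ymax, 2 * f1$Ymax, 1e-8)
  expect_rel_equal(f2$K_M, f1$K_M, 1e-8)
  expect_error(fit_hyperbola(x, rep(0.5, 5)), "degenerate")
})

test_that("noisy fits land near the generating truth under a fixed seed", {
  set.seed(42)
  x <- c(1, 3, 10, 25, 60, 150, 400, 600) * 1e-6
  y <- x / (x + 25e-6) + rnorm(8, 0, 0.02)
  expect_lt(abs(fit_hyperbola(x, y)$K_M - 25e-6) / 25e-6, 0.15)

  v <- seq(-0.09, 0.03, by = 0.012)
  yb <- 0.2 + 0.8 / (1 + exp((-0.03 - v) / 0.025)) + rnorm(length(v), 0, 0.03)
  expect_lt(abs(fit_boltzmann(v, yb)$V50 - (-0.03)), 0.010)
})

test_that("degenerate Boltzmann input is flagged, not fatal", {
  f <- suppressWarnings(fit_boltzmann(seq(-0.09, 0.03, 0.02), rep(1, 7)))
  expect_true(f$degenerate)
  expect_equal(f$Top, f$Bottom)
})

test_that("line fit matches the closed-form normal equations", {
  set.seed(7)
  x <- runif(12)
  y <- 2.5 * x - 1 + rnorm(12, 0, 0.1)
  f <- fit_line(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$intercept, beta[1], tolerance = 1e-12)
  expect_equal(f$slope, beta[2], tolerance = 1e-12)
  expect_error(fit_line(rep(1, 3), 1:3), "singular")
})

test_that("mono-exponential fit rejects implausible input", {
  expect_error(fit_monoexp(1:3, c(1, 2, 3)), "length|least 4")
  # decaying data would imply a negative rate: the offset+rise model fits
  # it with amplitude < 0 and positive rate instead, so check a clean case
  t <- seq(0, 2, 0.1)
  f <- fit_monoexp(t, 0.3 + 0.7 * (1 - exp(-1.5 * t)))
  expect_rel_equal(f$rate, 1.5, 1e-7)
  expect_rel_equal(f$offset, 0.3, 1e-6)
})

test_that("fits are deterministic given identical inputs", {
  x <- c(1, 5, 20, 80, 300) * 1e-6
  set.seed(11)
  y <- x / (x + 30e-6) + rnorm(5, 0, 0.01)
  f1 <- fit_hyperbola(x, y)
  f2 <- fit_hyperbola(x, y)
  expect_identical(f1$K_M, f2$K_M)
})

test_that("tidy and glance provide broom-style summaries", {
  f <- fit_line(c(0, 1, 2, 3), c(0.1, 1.9, 4.1, 5.9))
  td <- tidy(f)
  expect_setequal(td$term, c("slope", "intercept"))
  expect_true(all(is.finite(td$std.error)))
  g <- glance(f)
  expect_equal(g$nobs, 4)
  expect_equal(g$df.residual, 2)
})

test_that("nested F-test separates slope and intercept hypotheses", {
  x <- seq(-0.09, 0.03, by = 0.02)
  set.seed(21)
  y <- 2 + 5 * x + rnorm(length(x), 0, 0.1)
  same <- compare_lines_ftest(x, y, x, y)
  expect_lt(same$F[1], 1e-10)
  expect_gt(same$p.value[1], 0.999)

  # equal slopes, intercepts 10 sigma apart: slope test quiet, line test loud
  set.seed(3)
  sigma <- 0.05
  yA <- 1 + 5 * x + rnorm(length(x), 0, sigma)
  yB <- 1 + 10 * sigma + 5 * x + rnorm(length(x), 0, sigma)
  r <- compare_lines_ftest(x, yA, x, yB)
  expect_gt(r$p.value[r$hypothesis == "shared_slope"], 0.05)
  expect_lt(r$p.value[r$hypothesis == "shared_line"], 0.01)
  expect_error(compare_lines_ftest(1:2, 1:2, 1, 1), "insufficient")
})

test_that("normalization maps the reference to exactly 1 and round-trips", {
  d <- tibble::tibble(voltage = c(-0.09, -0.06), current = c(-60e-12, -40e-12))
  n <- normalize_to_reference(d, "current", "voltage", -0.06)
  expect_equal(n$current_norm, c(1.5, 1))
  expect_equal(n$current_norm * n$current[2], n$current, tolerance = 1e-15)
  allsame <- tibble::tibble(k = 1:3, v = c(2, 2, 2))
  expect_equal(normalize_to_reference(allsame, "v", "k", 2)$v_norm,
               rep(1, 3))
  expect_error(normalize_to_reference(
    tibble::tibble(k = 1, v = 0), "v", "k", 1), "zero")
  expect_error(normalize_to_reference(d, "current", "voltage", 99),
               "exactly one")
})
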