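#' Fit a rectangular hyperbola to a concentration-response series
#'
#' Fits `y = Ymax * x / (K_M + x)` by nonlinear least squares. The
#' initialization is deterministic: `Ymax` starts at `max(y)` and `K_M`
#' at the x-value where the response first crosses half of `max(y)`, so
#' fits are reproducible without seeds.
#'
#' @param x Concentrations (> 0, at least 3 distinct values).
#' @param y Responses.
#' @return Object of class `c("hyperbola_fit", "slc6_fit")` with elements
#'   `Ymax`, `K_M`, `residuals`, `sigma`, `fitted`, `data`.
#' @examples
#' x <- c(1, 3, 10, 30, 100, 300) * 1e-6
#' f <- fit_hyperbola(x, x / (x + 10e-6))
#' f$K_M # 1e-5
#' @export
fit_hyperbola <- function(x, y) {
  stopifnot(length(x) == length(y), length(unique(x)) >= 3, all(x > 0))
  if (diff(range(y)) == 0) stop("degenerate data: all responses equal")
  ymax0 <- max(y)
  half <- ymax0 / 2
  above <- which(y >= half)
  km0 <- if (length(above) > 0) max(x[which.min(abs(y - half))], min(x)) else
    stats::median(x)
  fit <- minpack.lm::nlsLM(y ~ Ymax * x / (K_M + x),
                           start = list(Ymax = ymax0, K_M = km0),
                           lower = c(-Inf, .Machine$double.xmin),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  new_slc6_fit("hyperbola_fit",
               params = list(Ymax = unname(cf["Ymax"]), K_M = unname(cf["K_M"])),
               fit = fit, x = x, y = y)
}

#' Fit a Boltzmann sigmoid to a voltage series
#'
#' Fits `y = Bottom + (Top - Bottom) / (1 + exp((V50 - x) / Slope))`.
#' Initialization: `Top`/`Bottom` from the data range ordered by the sign
#' of the overall trend, `V50` at the voltage where the data cross their
#' midpoint, `Slope` at a quarter of the voltage span. Degenerate
#' (flat) data fall back to `Top = Bottom = mean(y)` with a `degenerate`
#' flag instead of erroring.
#'
#' @param x Voltages (V; at least 4 points).
#' @param y Responses.
#' @return Object of class `c("boltzmann_fit", "slc6_fit")` with `Top`,
#'   `Bottom`, `V50`, `Slope` and a logical `degenerate` element.
#' @export
fit_boltzmann <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  span <- diff(range(y))
  if (span < 1e-12 * max(1, max(abs(y)))) {
    f <- new_slc6_fit("boltzmann_fit",
                      params = list(Top = mean(y), Bottom = mean(y),
                                    V50 = mean(x), Slope = diff(range(x)) / 4),
                      fit = NULL, x = x, y = y)
    f$degenerate <- TRUE
    warning("constant data: Boltzmann fit degenerate (Top = Bottom)")
    return(f)
  }
  increasing <- stats::coef(stats::lm(y ~ x))[2] > 0
  top0 <- if (increasing) max(y) else min(y)
  bot0 <- if (increasing) min(y) else max(y)
  mid <- (max(y) + min(y)) / 2
  v50_0 <- x[which.min(abs(y - mid))]
  slope0 <- diff(range(x)) / 4
  fit <- try(minpack.lm::nlsLM(
    y ~ Bottom + (Top - Bottom) / (1 + exp((V50 - x) / Slope)),
    start = list(Top = top0, Bottom = bot0, V50 = v50_0, Slope = slope0),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    f <- new_slc6_fit("boltzmann_fit",
                      params = list(Top = top0, Bottom = bot0, V50 = v50_0,
                                    Slope = slope0),
                      fit = NULL, x = x, y = y)
    f$degenerate <- TRUE
    warning("Boltzmann fit failed to converge; returning initial values ",
            "with degenerate flag")
    return(f)
  }
  cf <- as.list(stats::coef(fit))
  f <- new_slc6_fit("boltzmann_fit", params = cf, fit = fit, x = x, y = y)
  f$degenerate <- FALSE
  f
}

#' Fit a straight line (closed-form least squares)
#'
#' @param x,y Data (at least 2 points, non-singular design).
#' @return Object of class `c("line_fit", "slc6_fit")` with `slope`,
#'   `intercept` and the coefficient covariance matrix `vcov`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (diff(range(x)) == 0) stop("singular design: all x equal")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  f <- new_slc6_fit("line_fit",
                    params = list(slope = unname(cf[2]),
                                  intercept = unname(cf[1])),
                    fit = fit, x = x, y = y)
  f$vcov <- stats::vcov(fit)
  f
}

#' Fit a rising mono-exponential
#'
#' Fits `y = offset + amplitude * (1 - exp(-rate * t))` by nonlinear least
#' squares with a deterministic log-linear initialization: the plateau is
#' taken as `max(y)` and `log(plateau - y)` is regressed on `t` to seed the
#' rate. A negative fitted rate is an error (the recovery protocols this
#' serves are non-decreasing in time).
#'
#' @param t Times (s; at least 4 points).
#' @param y Responses (bounded).
#' @return Object of class `c("monoexp_fit", "slc6_fit")` with `rate`
#'   (s^-1), `amplitude`, `offset`.
#' @examples
#' t <- seq(0, 3, 0.25)
#' fit_monoexp(t, 1 - exp(-2 * t))$rate # 2
#' @export
fit_monoexp <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 4, all(is.finite(y)))
  plateau <- max(y)
  resid0 <- plateau - y + 1e-12 * max(1, abs(plateau))
  pos <- resid0 > 0 & y < plateau
  rate0 <- if (sum(pos) >= 2) {
    r <- -stats::coef(stats::lm(log(resid0[pos]) ~ t[pos]))[2]
    if (!is.finite(r) || r <= 0) 1 / max(t) else unname(r)
  } else 1 / max(t)
  fit <- minpack.lm::nlsLM(
    y ~ offset + amplitude * (1 - exp(-rate * t)),
    start = list(offset = min(y), amplitude = plateau - min(y), rate = rate0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- as.list(stats::coef(fit))
  if (cf$rate <= 0) stop("mono-exponential fit returned a non-positive rate")
  new_slc6_fit("monoexp_fit",
               params = list(rate = cf$rate, amplitude = cf$amplitude,
                             offset = cf$offset),
               fit = fit, x = t, y = y)
}

new_slc6_fit <- function(class1, params, fit, x, y) {
  fitted_vals <- if (!is.null(fit)) as.numeric(stats::fitted(fit)) else
    rep(mean(y), length(y))
  res <- y - fitted_vals
  structure(c(params, list(
    residuals = res,
    sigma = if (length(y) > length(params)) {
      sqrt(sum(res^2) / (length(y) - length(params)))
    } else NA_real_,
    fitted = fitted_vals,
    data = tibble::tibble(x = x, y = y),
    nls = fit
  )), class = c(class1, "slc6_fit"))
}

#' @export
print.slc6_fit <- function(x, ...) {
  cls <- class(x)[1]
  pars <- x[setdiff(names(x), c("residuals", "sigma", "fitted", "data",
                                "nls", "vcov", "degenerate"))]
  cat("<", cls, "> ", paste(sprintf("%s = %.6g", names(pars),
                                    unlist(pars)), collapse = ", "),
      "\n  residual SD: ", format(x$sigma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted curve object
#'
#' broom-style one-row-per-parameter summary. Standard errors come from
#' the underlying least-squares fit where available.
#'
#' @param x A fit returned by [fit_hyperbola()], [fit_boltzmann()],
#'   [fit_line()] or [fit_monoexp()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.slc6_fit <- function(x, ...) {
  pars <- x[setdiff(names(x), c("residuals", "sigma", "fitted", "data",
                                "nls", "vcov", "degenerate"))]
  se <- rep(NA_real_, length(pars))
  if (!is.null(x$nls)) {
    sm <- try(summary(x$nls)$coefficients, silent = TRUE)
    if (!inherits(sm, "try-error")) {
      nm_map <- c(slope = "x", intercept = "(Intercept)")
      for (i in seq_along(pars)) {
        key <- names(pars)[i]
        row <- if (key %in% names(nm_map)) nm_map[[key]] else key
        if (row %in% rownames(sm)) se[i] <- sm[row, "Std. Error"]
      }
    }
  }
  tibble::tibble(term = names(pars), estimate = unlist(pars, use.names = FALSE),
                 std.error = se)
}

#' Glance at a fitted curve object
#'
#' @inheritParams tidy.slc6_fit
#' @return One-row tibble with `sigma`, `df.residual`, `nobs`.
#' @export
glance.slc6_fit <- function(x, ...) {
  n <- nrow(x$data)
  k <- nrow(tidy(x))
  tibble::tibble(sigma = x$sigma, df.residual = n - k, nobs = n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Nested F-test comparing two linear fits
#'
#' Compares two datasets fit by straight lines, testing first whether a
#' shared slope suffices (separate intercepts) and then whether a single
#' shared line (shared slope and intercept) suffices, each against fully
#' separate fits. This mirrors the way uptake-voltage relations under
#' different intracellular conditions are compared: slope equality asks
#' whether the voltage dependence differs, intercept equality whether the
#' overall level differs.
#'
#' @param xA,yA First dataset.
#' @param xB,yB Second dataset.
#' @return A tibble with one row per hypothesis (`"shared_slope"`,
#'   `"shared_line"`) and columns `F`, `df1`, `df2`, `p.value`.
#' @export
compare_lines_ftest <- function(xA, yA, xB, yB) {
  stopifnot(length(xA) == length(yA), length(xB) == length(yB))
  n <- length(xA) + length(xB)
  if (n < 5) stop("insufficient degrees of freedom for the nested F-test")
  g <- factor(c(rep("A", length(xA)), rep("B", length(xB))))
  x <- c(xA, xB)
  y <- c(yA, yB)
  full <- stats::lm(y ~ x * g)          # separate slopes and intercepts
  shared_slope <- stats::lm(y ~ x + g)  # common slope, separate intercepts
  shared_line <- stats::lm(y ~ x)       # single line
  av1 <- stats::anova(shared_slope, full)
  av2 <- stats::anova(shared_line, full)
  tibble::tibble(
    hypothesis = c("shared_slope", "shared_line"),
    F = c(av1$F[2], av2$F[2]),
    df1 = c(av1$Df[2], av2$Df[2]),
    df2 = c(av1$Res.Df[2], av2$Res.Df[2]),
    p.value = c(av1$`Pr(>F)`[2], av2$`Pr(>F)`[2])
  )
}

#' Normalize a series to a reference entry
#'
#' Divides every value by the value at the reference key, so the
#' reference maps to exactly 1 (the convention used for presenting
#' current-voltage and recovery series).
#'
#' @param data A data frame.
#' @param value Name of the value column.
#' @param key Name of the key column.
#' @param reference Key of the reference entry (must be present, value
#'   nonzero).
#' @param name Name of the new normalized column (default
#'   `paste0(value, "_norm")`).
#' @return The data frame with the normalized column appended.
#' @export
normalize_to_reference <- function(data, value, key, reference,
                                   name = paste0(value, "_norm")) {
  idx <- which(data[[key]] == reference)
  if (length(idx) != 1) stop("reference key must match exactly one row")
  ref <- data[[value]][idx]
  if (ref == 0) stop("reference value is zero; cannot normalize")
  data[[name]] <- data[[value]] / ref
  data
}
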