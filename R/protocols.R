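#' Simulate a single substrate application on a transporter model
#'
#' Convenience wrapper: builds the application protocol (exponential
#' solution exchange), starts from the resting steady state at the holding
#' potential in the substrate-free bath, integrates the master equation,
#' and returns the occupancy trajectory on a grid that is dense (2 ms)
#' around the application onset and wash-out and coarser elsewhere.
#'
#' @param model A `transporter_model` (see [build_dat_model()]).
#' @param conc Substrate concentration applied (M).
#' @param V Holding voltage (V).
#' @param conditions An [ion_conditions()] object or preset name.
#' @param duration Application duration (s, default 15).
#' @param t_on Onset time (s, default 0.5).
#' @param t_post Post-washout padding (s, default 1).
#' @param constants A [phys_constants()] bundle.
#' @return An `occupancy_trajectory` (see [integrate_occupancies()]).
#' @export
simulate_application <- function(model, conc, V,
                                 conditions = "physiological",
                                 duration = 15, t_on = 0.5, t_post = 1,
                                 constants = phys_constants()) {
  conditions <- resolve_conditions(conditions)
  protocol <- substrate_application(V, conc, t_on, duration)
  t_end <- t_on + duration + t_post
  t_grid <- application_grid(c(t_on, t_on + duration), t_end)
  integrate_occupancies(model$scheme, conditions, protocol,
                        t_grid = t_grid, constants = constants)
}

resolve_conditions <- function(conditions) {
  if (is.character(conditions)) get_condition_preset(conditions) else conditions
}

# output grid: 2 ms resolution for 0.35 s after each event, 20 ms elsewhere
application_grid <- function(events, t_end, fine = 0.002, coarse = 0.02,
                             fine_span = 0.35) {
  tt <- seq(0, t_end, by = coarse)
  for (ev in events) {
    if (ev < t_end) {
      tt <- c(tt, seq(ev, min(ev + fine_span, t_end), by = fine))
    }
  }
  sort(unique(round(tt, 6)))
}

#' Concentration-response of uptake and steady current
#'
#' For each concentration, simulates a 15 s application, extracts the
#' fluorescence-uptake slope and the steady-state current, normalizes both
#' readouts to the value at the reference concentration (600 uM when
#' present, else the highest tested), and fits a rectangular hyperbola to
#' each readout to estimate `K_M`.
#'
#' @inheritParams simulate_application
#' @param concentrations Concentrations (M), sorted, > 0. Default grid
#'   1-600 uM.
#' @param pop,channel Population and channel parameters.
#' @return A tibble of class `protocol_result` with one row per
#'   concentration (`concentration`, `uptake_slope`, `steady`, normalized
#'   columns) and attributes `fits` (named list of [fit_hyperbola()]
#'   results) and `reference`.
#' @export
run_concentration_response <- function(model,
                                       concentrations = c(1, 3, 10, 30, 100,
                                                          300, 600) * 1e-6,
                                       V = -0.060,
                                       conditions = "physiological",
                                       duration = 15,
                                       pop = population_params(),
                                       channel = channel_params(),
                                       constants = phys_constants()) {
  stopifnot(all(concentrations > 0))
  concentrations <- sort(concentrations)
  conditions <- resolve_conditions(conditions)
  rows <- purrr::map(concentrations, function(cc) {
    traj <- simulate_application(model, cc, V, conditions, duration,
                                 constants = constants)
    upt <- substrate_uptake(traj, pop)
    cur <- total_current(traj, channel, pop)
    tibble::tibble(
      concentration = cc,
      uptake_slope = extract_uptake_slope(upt, 0.5, 0.5 + duration),
      steady = extract_steady(cur, 0.5, 0.5 + duration)
    )
  })
  out <- dplyr::bind_rows(rows)
  ref <- if (600e-6 %in% concentrations) 600e-6 else max(concentrations)
  out <- normalize_to_reference(out, "uptake_slope", "concentration", ref)
  if (out$steady[out$concentration == ref] != 0) {
    out <- normalize_to_reference(out, "steady", "concentration", ref)
  }
  fits <- list(uptake = fit_hyperbola(out$concentration, out$uptake_slope))
  if (any(out$steady != 0) && diff(range(out$steady)) > 0) {
    fits$steady <- try(fit_hyperbola(out$concentration, abs(out$steady)),
                       silent = TRUE)
    if (inherits(fits$steady, "try-error")) fits$steady <- NULL
  }
  as_protocol_result(out, fits = fits, reference = ref)
}

#' Current-voltage and uptake-voltage relationships
#'
#' Simulates one application per voltage, extracting the uptake slope
#' (normalized to the -90 mV value) and the peak and steady currents
#' (normalized to -60 mV when present in the grid, else to the most
#' negative voltage). Both a Boltzmann sigmoid and a line are fitted to
#' each normalized series; the model with the smaller residual SD is
#' reported as `preferred`, with both fits stored.
#'
#' @inheritParams run_concentration_response
#' @param voltages Voltage grid (V); default -90 to +30 mV in 20 mV steps.
#' @param concentration Substrate concentration (M, default 30 uM).
#' @return A `protocol_result` tibble with one row per voltage and
#'   attributes `fits` (per readout, both candidate fits and the preferred
#'   label) and `references`.
#' @export
run_iv <- function(model,
                   voltages = seq(-0.090, 0.030, by = 0.020),
                   concentration = 30e-6,
                   conditions = "physiological",
                   duration = 15,
                   pop = population_params(),
                   channel = channel_params(),
                   constants = phys_constants()) {
  if (length(voltages) == 0) stop("empty voltage grid")
  conditions <- resolve_conditions(conditions)
  rows <- purrr::map(voltages, function(vv) {
    traj <- simulate_application(model, concentration, vv, conditions,
                                 duration, constants = constants)
    upt <- substrate_uptake(traj, pop)
    cur <- total_current(traj, channel, pop)
    tibble::tibble(
      voltage = vv,
      uptake_slope = extract_uptake_slope(upt, 0.5, 0.5 + duration),
      peak = extract_peak(cur, 0.5),
      steady = extract_steady(cur, 0.5, 0.5 + duration)
    )
  })
  out <- dplyr::bind_rows(rows)
  v_up_ref <- if (-0.090 %in% voltages) -0.090 else min(voltages)
  v_i_ref <- if (-0.060 %in% voltages) -0.060 else min(voltages)
  out <- normalize_to_reference(out, "uptake_slope", "voltage", v_up_ref)
  cur_ok <- all(is.finite(out$peak)) && out$peak[out$voltage == v_i_ref] != 0
  if (cur_ok) {
    out <- normalize_to_reference(out, "peak", "voltage", v_i_ref)
  }
  if (out$steady[out$voltage == v_i_ref] != 0) {
    out <- normalize_to_reference(out, "steady", "voltage", v_i_ref)
  }
  fits <- list(uptake = best_voltage_fit(out$voltage, out$uptake_slope_norm))
  if ("peak_norm" %in% names(out)) {
    fits$peak <- best_voltage_fit(out$voltage, out$peak_norm)
  }
  as_protocol_result(out, fits = fits,
                     references = c(uptake = v_up_ref, current = v_i_ref))
}

# fit both candidate families; keep the one with the lower residual SD
best_voltage_fit <- function(v, y) {
  line <- fit_line(v, y)
  boltz <- suppressWarnings(try(fit_boltzmann(v, y), silent = TRUE))
  if (inherits(boltz, "try-error") || isTRUE(boltz$degenerate)) {
    return(list(line = line, boltzmann = NULL, preferred = "line"))
  }
  pick <- if (is.na(boltz$sigma) || line$sigma <= boltz$sigma) "line" else
    "boltzmann"
  list(line = line, boltzmann = boltz, preferred = pick)
}

#' Two-pulse turnover-recovery protocol
#'
#' A reference substrate pulse recruits transporters into the cycle; after
#' a variable wash-out interval a test pulse probes how many have completed
#' the cycle and returned to the outward-facing conformation. The test
#' peak, normalized to the reference peak, recovers mono-exponentially
#' with the catalytic (cycle-completion) rate.
#'
#' @inheritParams run_iv
#' @param wash_times Wash-out intervals (s). The default log-spaced grid
#'   (0.05-60 s) covers ~5 recovery time constants for turnover rates
#'   between ~0.1 and ~5 per second, the range spanned by the shipped
#'   models.
#' @param pulse_duration Pulse length (s). Default 2 s for NET (slow
#'   turnover requires a longer pulse to recruit the cycle), 0.5 s
#'   otherwise.
#' @return A `protocol_result` tibble (`wash_time`, `peak_ref`,
#'   `peak_test`, `recovery`) with attributes `fit` (a [fit_monoexp()]
#'   result) and `recovery_rate` (s^-1).
#' @export
run_two_pulse <- function(model,
                          wash_times = exp(seq(log(0.05), log(60),
                                               length.out = 12)),
                          concentration = 30e-6,
                          V = -0.060,
                          conditions = "physiological",
                          pulse_duration = NULL,
                          pop = population_params(),
                          channel = channel_params(),
                          constants = phys_constants()) {
  stopifnot(all(wash_times > 0))
  conditions <- resolve_conditions(conditions)
  if (is.null(pulse_duration)) {
    pulse_duration <- if (identical(model$id, "NET")) 2 else 0.5
  }
  t_on <- 0.2
  rows <- purrr::map(sort(wash_times), function(w) {
    w <- round(w, 3)  # align segment boundaries with the ms output grid
    on2 <- t_on + pulse_duration + w
    protocol <- application_protocol(V, list(
      list(t_start = t_on, t_end = t_on + pulse_duration,
           targets = c(S = concentration)),
      list(t_start = on2, t_end = on2 + pulse_duration,
           targets = c(S = concentration))
    ))
    t_end <- on2 + pulse_duration + 0.1
    grid <- application_grid(c(t_on, t_on + pulse_duration, on2), t_end)
    traj <- integrate_occupancies(model$scheme, conditions, protocol,
                                  t_grid = grid, constants = constants)
    cur <- total_current(traj, channel, pop)
    p_ref <- extract_peak(cur, t_on)
    p_test <- extract_peak(cur, on2)
    tibble::tibble(wash_time = w, peak_ref = p_ref, peak_test = p_test)
  })
  out <- dplyr::bind_rows(rows)
  if (max(abs(out$peak_ref)) < 1e-18) {
    stop("reference peak below numeric floor; cannot normalize recovery")
  }
  out$recovery <- out$peak_test / out$peak_ref
  fit <- fit_monoexp(out$wash_time, out$recovery)
  as_protocol_result(out, fit = fit, recovery_rate = fit$rate)
}

#' Run a protocol across intracellular ion-condition presets
#'
#' Applies one of the virtual protocols under each named preset and binds
#' the results into one tidy long table keyed by preset, for
#' cross-condition comparisons (e.g. uptake-voltage lines with and without
#' intracellular K+).
#'
#' @inheritParams run_iv
#' @param presets Character vector of preset names
#'   (see [get_condition_preset()]).
#' @param protocol One of `"iv"`, `"concentration_response"`,
#'   `"two_pulse"`.
#' @param ... Passed to the underlying protocol function.
#' @return A tibble with a `preset` column followed by the protocol's
#'   columns; per-preset attributes are collected in the `runs` attribute
#'   (a named list of the full `protocol_result` objects).
#' @export
run_ion_sweep <- function(model, presets,
                          protocol = c("iv", "concentration_response",
                                       "two_pulse"),
                          ...) {
  protocol <- match.arg(protocol)
  fn <- switch(protocol, iv = run_iv,
               concentration_response = run_concentration_response,
               two_pulse = run_two_pulse)
  runs <- purrr::map(presets, function(ps) {
    fn(model, conditions = get_condition_preset(ps), ...)
  })
  names(runs) <- presets
  out <- purrr::map2(presets, runs, function(ps, r) {
    dplyr::bind_cols(tibble::tibble(preset = ps), tibble::as_tibble(r))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "runs") <- runs
  out
}

as_protocol_result <- function(data, ...) {
  out <- tibble::as_tibble(data)
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("protocol_result", class(out))
  out
}

#' Extract the attached fit(s) from a protocol result
#'
#' @param result A `protocol_result` tibble.
#' @return The `fits` (or `fit`) attribute.
#' @export
protocol_fits <- function(result) {
  f <- attr(result, "fits")
  if (is.null(f)) f <- attr(result, "fit")
  f
}
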