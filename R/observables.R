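#' Population and channel parameters for current observables
#'
#' @param NC Number of transporters per cell (default 4e6).
#' @return List of class `population_params`.
#' @export
population_params <- function(NC = 4e6) {
  stopifnot(NC > 0)
  structure(list(NC = NC), class = "population_params")
}

#' @rdname population_params
#' @param gamma Single-channel conductance of the conducting state, S
#'   (default 2.4 pS).
#' @param V_rev Reversal potential of the conducting state, V (default
#'   +100 mV, the Na+ reversal potential).
#' @param conducting_state Optional override of the conducting-state name
#'   (defaults to the scheme annotation).
#' @export
channel_params <- function(gamma = 2.4e-12, V_rev = 0.100,
                           conducting_state = NULL) {
  stopifnot(gamma > 0)
  structure(list(gamma = gamma, V_rev = V_rev,
                 conducting_state = conducting_state),
            class = "channel_params")
}

# per-edge effective rates at each trajectory time (handles time-varying
# external concentrations); returns list(fwd, rev) matrices [time x edge]
edge_rate_matrix <- function(traj) {
  ctx <- traj_context(traj)
  scheme <- ctx$scheme
  tr <- scheme$transitions
  V <- ctx$protocol$V
  constants <- ctx$constants
  kf_v <- voltage_scaled_rate(tr$kf0, tr$zQ, V, constants, "fwd")
  kr_v <- voltage_scaled_rate(tr$kr0, tr$zQ, V, constants, "rev")
  ext <- external_concentrations(ctx$protocol, ctx$conditions, traj$time)
  one <- matrix(1, nrow(ext), nrow(tr))
  fwd <- one %*% diag(kf_v, nrow(tr))
  rev <- one %*% diag(kr_v, nrow(tr))
  for (e in seq_len(nrow(tr))) {
    if (!is.na(tr$lig_f[e])) {
      fwd[, e] <- fwd[, e] * (if (tr$side_f[e] == "in")
        ctx$conditions$inside[tr$lig_f[e]] else ext[, tr$lig_f[e]])
    }
    if (!is.na(tr$lig_r[e])) {
      rev[, e] <- rev[, e] * (if (tr$side_r[e] == "in")
        ctx$conditions$inside[tr$lig_r[e]] else ext[, tr$lig_r[e]])
    }
  }
  list(fwd = fwd, rev = rev)
}

#' Coupled membrane current of a transporter population
#'
#' The current stoichiometrically tied to the transport cycle:
#' `I = -F * NC / N_A * sum_ij zQ_ij (p_i k_ij - p_j k_ji)`, summed over
#' every transition with nonzero equivalent charge, evaluated pointwise
#' along the trajectory. Inward current is negative. At thermodynamic
#' equilibrium every edge flux vanishes and the coupled current is zero.
#'
#' @param traj An `occupancy_trajectory` from [integrate_occupancies()]
#'   (carries its scheme/conditions/protocol context).
#' @param pop A [population_params()] object.
#' @return A tibble of class `current_trace` with columns `time`,
#'   `current` (A) and `component = "coupled"`.
#' @export
coupled_current <- function(traj, pop = population_params()) {
  ctx <- traj_context(traj)
  scheme <- ctx$scheme
  tr <- scheme$transitions
  nm <- scheme$states$name
  rates <- edge_rate_matrix(traj)
  P <- as.matrix(tibble::as_tibble(traj)[, nm])
  ii <- match(tr$from, nm)
  jj <- match(tr$to, nm)
  flux <- rates$fwd * P[, ii, drop = FALSE] - rates$rev * P[, jj, drop = FALSE]
  constants <- ctx$constants
  I <- -constants$F * pop$NC / constants$NA_ *
    as.numeric(flux %*% tr$zQ)
  new_current_trace(traj$time, I, "coupled")
}

#' Uncoupled (channel-like) membrane current
#'
#' Current through the Na+-permeable conducting state:
#' `I = P_o * gamma * NC * (V - V_rev)`, where `P_o` is the occupancy of
#' the conducting state. Returns an identically zero trace if the scheme
#' has no conducting state.
#'
#' @inheritParams coupled_current
#' @param channel A [channel_params()] object.
#' @return A `current_trace` tibble with `component = "uncoupled"`.
#' @export
uncoupled_current <- function(traj, channel = channel_params(),
                              pop = population_params()) {
  ctx <- traj_context(traj)
  cs <- channel$conducting_state
  if (is.null(cs)) cs <- ctx$scheme$meta$conducting_state
  V <- ctx$protocol$V
  if (is.null(cs) || is.na(cs) || !cs %in% ctx$scheme$states$name) {
    return(new_current_trace(traj$time, rep(0, nrow(traj)), "uncoupled"))
  }
  I <- traj[[cs]] * channel$gamma * pop$NC * (V - channel$V_rev)
  new_current_trace(traj$time, I, "uncoupled")
}

#' Total membrane current (coupled + uncoupled)
#'
#' @inheritParams uncoupled_current
#' @return A `current_trace` tibble with `component = "total"`.
#' @export
total_current <- function(traj, channel = channel_params(),
                          pop = population_params()) {
  a <- coupled_current(traj, pop)
  b <- uncoupled_current(traj, channel, pop)
  new_current_trace(a$time, a$current + b$current, "total")
}

new_current_trace <- function(time, current, component) {
  out <- tibble::tibble(time = time, current = current,
                        component = component)
  class(out) <- c("current_trace", class(out))
  out
}

#' Fluorescence-reported substrate uptake
#'
#' Net inward substrate flux through the intracellular release step,
#' `flux = (p_TiClS * koff_S_in - p_TiCl * kon_S_in * S_in) * NC`
#' (molecules per second), together with its running integral, the
#' cumulative number of accumulated substrate molecules. The intracellular
#' substrate concentration is held fixed (default 0: dilution into a large
#' cell volume) unless `cell_volume_L` is given, in which case accumulated
#' substrate back-feeds `S_in`. A single multiplicative `brightness`
#' converts molecules to fluorescence arbitrary units.
#'
#' @inheritParams coupled_current
#' @param brightness Arbitrary-unit scaling per molecule (default 1).
#' @param cell_volume_L Optional finite cell volume (L); when given, the
#'   intracellular substrate concentration grows with accumulation.
#' @return A tibble of class `fluorescence_trace` with columns `time`,
#'   `flux` (molecules/s), `cumulative` (molecules) and `fluorescence`
#'   (AU).
#' @export
substrate_uptake <- function(traj, pop = population_params(),
                             brightness = 1, cell_volume_L = NULL) {
  ctx <- traj_context(traj)
  meta <- ctx$scheme$meta
  need <- c("substrate_bound_in", "substrate_free_in",
            "substrate_koff_in", "substrate_kon_in")
  if (!all(need %in% names(meta))) {
    stop("scheme lacks uptake annotations (", paste(need, collapse = ", "), ")")
  }
  sb <- meta$substrate_bound_in
  sf <- meta$substrate_free_in
  if (!all(c(sb, sf) %in% ctx$scheme$states$name)) {
    stop("annotated uptake states not present in scheme")
  }
  # effective rates of the intracellular release edge (voltage-scaled, so
  # the reported flux is exactly the net flux through that transition)
  tr <- ctx$scheme$transitions
  e <- which(tr$from == sb & tr$to == sf)
  release_dir <- "fwd"
  if (length(e) == 0) {  # release edge stored in the binding orientation
    e <- which(tr$from == sf & tr$to == sb)
    release_dir <- "rev"
  }
  if (length(e) != 1) stop("no release transition ", sb, " -> ", sf)
  V <- ctx$protocol$V
  koff <- voltage_scaled_rate(meta$substrate_koff_in, tr$zQ[e], V,
                              ctx$constants, release_dir)
  kon <- voltage_scaled_rate(meta$substrate_kon_in, tr$zQ[e], V,
                             ctx$constants,
                             if (release_dir == "fwd") "rev" else "fwd")
  tt <- traj$time
  n <- length(tt)
  if (is.null(cell_volume_L)) {
    S_in <- unname(ctx$conditions$inside["S"])
    flux <- (traj[[sb]] * koff - traj[[sf]] * kon * S_in) * pop$NC
    cumulative <- c(0, cumsum(diff(tt) * (flux[-1] + flux[-n]) / 2))
  } else {
    constants <- ctx$constants
    # accumulate with back-reaction: S_in(t) from the running integral
    S_in <- numeric(n)
    flux <- numeric(n)
    cumulative <- numeric(n)
    S_in[1] <- unname(ctx$conditions$inside["S"])
    flux[1] <- (traj[[sb]][1] * koff - traj[[sf]][1] * kon * S_in[1]) * pop$NC
    for (k in 2:n) {
      dt <- tt[k] - tt[k - 1]
      cumulative[k] <- cumulative[k - 1] + dt * flux[k - 1]
      S_in[k] <- unname(ctx$conditions$inside["S"]) +
        cumulative[k] / constants$NA_ / cell_volume_L
      flux[k] <- (traj[[sb]][k] * koff - traj[[sf]][k] * kon * S_in[k]) * pop$NC
    }
  }
  out <- tibble::tibble(time = tt, flux = flux, cumulative = cumulative,
                        fluorescence = brightness * cumulative)
  class(out) <- c("fluorescence_trace", class(out))
  out
}

#' Extract the peak (transient) current amplitude
#'
#' Baseline-subtracted extremum of the current within the first 200 ms
#' after application onset. The baseline is the mean current over the
#' 100 ms preceding onset (or from the first sample if the trace starts at
#' onset). The sign of the peak is preserved (inward peaks are negative).
#'
#' @param trace A `current_trace` tibble.
#' @param onset Application onset time (s).
#' @param window Width of the search window after onset (s, default 0.2).
#' @return Peak amplitude in A.
#' @export
extract_peak <- function(trace, onset, window = 0.2) {
  tt <- trace$time
  if (onset < tt[1] || onset > tt[length(tt)]) {
    stop("onset outside the trace time grid")
  }
  base_sel <- tt >= onset - 0.1 & tt < onset
  baseline <- if (any(base_sel)) mean(trace$current[base_sel]) else
    trace$current[1]
  sel <- tt >= onset & tt <= onset + window
  if (!any(sel)) stop("search window outside the trace time grid")
  dev <- trace$current[sel] - baseline
  dev[which.max(abs(dev))]
}

#' Extract the steady-state current amplitude
#'
#' Baseline-subtracted mean current over the final 20% of the application
#' window, where the transient has relaxed and persistent cycling (and any
#' uncoupled conductance) sets the current.
#'
#' @param trace A `current_trace` tibble.
#' @param t_start,t_end Application window (s).
#' @return Steady amplitude in A.
#' @export
extract_steady <- function(trace, t_start, t_end) {
  tt <- trace$time
  if (t_start < tt[1] || t_end > tt[length(tt)] || t_end <= t_start) {
    stop("application window outside the trace time grid")
  }
  base_sel <- tt >= t_start - 0.1 & tt < t_start
  baseline <- if (any(base_sel)) mean(trace$current[base_sel]) else
    trace$current[1]
  sel <- tt >= t_end - 0.2 * (t_end - t_start) & tt <= t_end
  mean(trace$current[sel]) - baseline
}

#' Extract the uptake rate as the slope of the fluorescence ramp
#'
#' Least-squares linear slope of the cumulative trace over a window inside
#' the application, excluding 0.5 s at each edge so that the solution
#' exchange transient and wash-out do not bias the estimate.
#'
#' @param trace A `fluorescence_trace` tibble (or any tibble with `time`
#'   and the named value column).
#' @param t_start,t_end Application window (s); the fitted window is
#'   `[t_start + 0.5, t_end - 0.5]`.
#' @param value Column to regress (default `"cumulative"`).
#' @return Slope in units of `value` per second.
#' @export
extract_uptake_slope <- function(trace, t_start, t_end,
                                 value = "cumulative") {
  lo <- t_start + 0.5
  hi <- t_end - 0.5
  if (hi - lo < 1) stop("uptake window shorter than 1 s after edge trimming")
  sel <- trace$time >= lo & trace$time <= hi
  if (sum(sel) < 3) stop("too few samples in uptake window")
  unname(stats::coef(stats::lm(trace[[value]][sel] ~ trace$time[sel]))[2])
}
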