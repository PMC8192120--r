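#' Voltage scaling of a rate constant over a symmetric energy barrier
#'
#' A transition that moves an equivalent charge `zQ` inward across the
#' membrane field is accelerated or decelerated by voltage following
#' `k = k0 * exp(-zQ*F*V / (2*R*T))` in the forward direction and the
#' reciprocal factor in the reverse direction (the barrier is assumed to sit
#' midway through the field). With `V` defined as intracellular minus
#' extracellular potential (volts), inward movement of positive charge is
#' fastest at hyperpolarized (negative) potentials.
#'
#' @param k0 Base rate constant at 0 mV (s^-1 or M^-1 s^-1).
#' @param zQ Equivalent elementary charge moved inward during the forward
#'   transition (dimensionless, may be fractional).
#' @param V Membrane voltage in volts.
#' @param constants A [phys_constants()] bundle.
#' @param direction `"fwd"` or `"rev"`.
#' @return The scaled rate, same units as `k0`. The product of the forward
#'   and reverse scaling factors is exactly 1 at every voltage.
#' @examples
#' voltage_scaled_rate(10, zQ = 1, V = -0.06) # ~32.8 s^-1
#' @export
voltage_scaled_rate <- function(k0, zQ, V, constants = phys_constants(),
                                direction = c("fwd", "rev")) {
  direction <- match.arg(direction)
  if (!all(is.finite(k0)) || !all(is.finite(zQ)) || !all(is.finite(V))) {
    stop("non-finite input to voltage_scaled_rate")
  }
  if (any(k0 < 0)) stop("k0 must be non-negative")
  expo <- -zQ * constants$F * V / (2 * constants$R * constants$T)
  if (direction == "rev") expo <- -expo
  k0 * exp(expo)
}

# effective per-edge rates (pseudo-first-order) for a fixed external
# concentration vector; internal concentrations come from `conditions`.
# Returns list(fwd, rev) aligned with scheme$transitions rows.
edge_rates <- function(scheme, conditions, V, constants = phys_constants(),
                       ext = NULL) {
  tr <- scheme$transitions
  if (is.null(ext)) ext <- conditions$outside
  mult <- function(lig, side) {
    m <- rep(1, nrow(tr))
    has <- !is.na(lig)
    if (any(has)) {
      bad <- setdiff(lig[has], LIGAND_SPECIES)
      if (length(bad) > 0) {
        stop("ligand coupling references unknown species: ",
             paste(bad, collapse = ", "))
      }
      m[has] <- ifelse(side[has] == "in",
                       conditions$inside[lig[has]],
                       ext[lig[has]])
    }
    m
  }
  list(
    fwd = voltage_scaled_rate(tr$kf0, tr$zQ, V, constants, "fwd") *
      mult(tr$lig_f, tr$side_f),
    rev = voltage_scaled_rate(tr$kr0, tr$zQ, V, constants, "rev") *
      mult(tr$lig_r, tr$side_r)
  )
}

#' Assemble the master-equation generator of a scheme
#'
#' Builds the rate matrix `Q` such that `dp/dt = Q %*% p`, with
#' ligand-coupled rates multiplied by the relevant concentration
#' (pseudo-first-order) and all rates voltage-scaled. Columns sum to zero,
#' which is what conserves total probability.
#'
#' @inheritParams voltage_scaled_rate
#' @param scheme A [kinetic_scheme()].
#' @param conditions An [ion_conditions()] object.
#' @return A square matrix over states (dimnames = state names).
#' @export
build_generator <- function(scheme, conditions, V,
                            constants = phys_constants()) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(conditions, "ion_conditions"))
  n <- nrow(scheme$states)
  nm <- scheme$states$name
  ii <- match(scheme$transitions$from, nm)
  jj <- match(scheme$transitions$to, nm)
  r <- edge_rates(scheme, conditions, V, constants)
  Q <- matrix(0, n, n, dimnames = list(nm, nm))
  Q[cbind(jj, ii)] <- r$fwd
  Q[cbind(ii, jj)] <- r$rev
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Stationary occupancy distribution of a scheme
#'
#' Solves `Q p = 0` with `sum(p) = 1` by singular-value decomposition of
#' the generator. A disconnected scheme has a degenerate null space and is
#' rejected.
#'
#' @inheritParams build_generator
#' @return Named numeric vector of state occupancies (all `>= 0`, sum 1).
#' @examples
#' steady_state(two_state_scheme(2, 1),
#'              ion_conditions(), V = 0) # (1/3, 2/3)
#' @export
steady_state <- function(scheme, conditions, V, constants = phys_constants()) {
  Q <- build_generator(scheme, conditions, V, constants)
  n <- nrow(Q)
  sv <- svd(Q)
  d <- sv$d
  scale <- max(d)
  if (n > 1 && d[n - 1] < 1e-10 * scale) {
    stop("stationary distribution is not unique (disconnected scheme?)")
  }
  p <- sv$v[, n]
  p <- p / sum(p)
  if (any(p < -1e-9)) stop("steady-state solve produced negative occupancy")
  p[p < 0] <- 0
  p <- p / sum(p)
  stats::setNames(p, rownames(Q))
}

#' Define a voltage-clamp application protocol
#'
#' A protocol holds the clamped voltage and an ordered set of
#' non-overlapping segments during which the external concentrations of
#' named species are driven toward target values. Solution exchange is
#' never instantaneous: concentrations relax exponentially toward the
#' current target with time constant `tau_app` (10 ms by default, matching
#' the speed of a rapid superfusion system). Outside all segments the
#' targets revert to the bath (pre-application) solution.
#'
#' @param V Holding voltage, volts.
#' @param segments List of `list(t_start =, t_end =, targets = c(S = ...))`
#'   entries; `targets` is a named numeric vector of external
#'   concentrations (M).
#' @param tau_app Solution exchange time constant, s.
#' @return An object of class `application_protocol`.
#' @seealso [substrate_application()] for the common single-pulse case.
#' @export
application_protocol <- function(V, segments = list(), tau_app = 0.010) {
  stopifnot(is.finite(V), tau_app > 0)
  if (length(segments) > 0) {
    t0 <- vapply(segments, `[[`, 0, "t_start")
    t1 <- vapply(segments, `[[`, 0, "t_end")
    ord <- order(t0)
    segments <- segments[ord]
    t0 <- t0[ord]; t1 <- t1[ord]
    if (any(t1 <= t0)) stop("segment t_end must exceed t_start")
    if (length(t0) > 1 && any(t0[-1] < t1[-length(t1)])) {
      stop("protocol segments overlap")
    }
  }
  structure(list(V = V, segments = segments, tau_app = tau_app),
            class = "application_protocol")
}

#' @rdname application_protocol
#' @param conc Substrate concentration applied (M).
#' @param t_on Application onset time (s).
#' @param duration Application duration (s).
#' @export
substrate_application <- function(V, conc, t_on = 0.5, duration = 15,
                                  tau_app = 0.010) {
  application_protocol(V, list(list(t_start = t_on, t_end = t_on + duration,
                                    targets = c(S = conc))), tau_app)
}

# piecewise-analytic external concentration of every species at times t.
# Targets are piecewise constant; the actual concentration relaxes
# exponentially toward the current target with tau_app. Returns a matrix
# length(t) x species.
external_concentrations <- function(protocol, conditions, t) {
  base <- conditions$outside
  segs <- protocol$segments
  tau <- protocol$tau_app
  # boundaries of piecewise-constant target regions
  bounds <- sort(unique(c(0, unlist(lapply(segs, function(s)
    c(s$t_start, s$t_end))))))
  bounds <- bounds[bounds >= 0]
  target_at <- function(tt) {
    tg <- base
    for (s in segs) {
      if (tt >= s$t_start && tt < s$t_end) {
        tg[names(s$targets)] <- s$targets
      }
    }
    tg
  }
  # concentrations at region boundaries by forward recursion (start at base)
  c_b <- matrix(NA_real_, length(bounds), length(base),
                dimnames = list(NULL, names(base)))
  c_b[1, ] <- base
  if (length(bounds) > 1) {
    for (k in seq_len(length(bounds) - 1)) {
      tg <- target_at(bounds[k])
      dt <- bounds[k + 1] - bounds[k]
      c_b[k + 1, ] <- tg + (c_b[k, ] - tg) * exp(-dt / tau)
    }
  }
  out <- matrix(NA_real_, length(t), length(base),
                dimnames = list(NULL, names(base)))
  idx <- findInterval(t, bounds)
  idx[idx < 1] <- 1
  for (k in unique(idx)) {
    sel <- idx == k
    tg <- target_at(bounds[k])
    out[sel, ] <- rep(tg, each = sum(sel)) +
      (rep(c_b[k, ] - tg, each = sum(sel))) *
      exp(-(t[sel] - bounds[k]) / tau)
  }
  out
}

#' Integrate state occupancies under an application protocol
#'
#' Numerically integrates the master equation `dp/dt = Q(t) p` with the
#' generator rebuilt continuously as the external concentrations relax
#' toward the protocol targets. Integration uses a stiff-capable
#' adaptive-step solver (absolute tolerance 1e-10, relative 1e-8) and is
#' restarted at every segment boundary. Probability is conserved by
#' construction; drift beyond 1e-6 is treated as an integrator failure.
#'
#' @inheritParams build_generator
#' @param protocol An [application_protocol()]; its `V` is used.
#' @param p0 Initial occupancies (named, sums to 1). Defaults to the steady
#'   state at the holding potential in the pre-application solution.
#' @param t_grid Output times (s), increasing, starting at >= 0.
#' @return A tibble of class `occupancy_trajectory`: column `time` plus one
#'   occupancy column per state. The scheme, conditions, protocol and
#'   constants used are attached as the `context` attribute.
#' @export
integrate_occupancies <- function(scheme, conditions, protocol,
                                  p0 = NULL, t_grid,
                                  constants = phys_constants()) {
  stopifnot(inherits(protocol, "application_protocol"))
  nm <- scheme$states$name
  n <- length(nm)
  if (is.null(p0)) {
    p0 <- steady_state(scheme, conditions, protocol$V, constants)
  }
  if (abs(sum(p0) - 1) > 1e-8) stop("initial occupancies must sum to 1")
  p0 <- p0[nm]
  t_grid <- sort(unique(t_grid))
  stopifnot(t_grid[1] >= 0)

  ii <- match(scheme$transitions$from, nm)
  jj <- match(scheme$transitions$to, nm)
  V <- protocol$V
  # voltage factors and internal-ligand multipliers are time-invariant;
  # only external ligand concentrations vary with t
  tr <- scheme$transitions
  kf_v <- voltage_scaled_rate(tr$kf0, tr$zQ, V, constants, "fwd")
  kr_v <- voltage_scaled_rate(tr$kr0, tr$zQ, V, constants, "rev")
  side_mult <- function(lig, side, k) {
    has_in <- !is.na(lig) & side == "in"
    k[has_in] <- k[has_in] * conditions$inside[lig[has_in]]
    k
  }
  kf_v <- side_mult(tr$lig_f, tr$side_f, kf_v)
  kr_v <- side_mult(tr$lig_r, tr$side_r, kr_v)
  ext_f <- which(!is.na(tr$lig_f) & tr$side_f == "out")
  ext_r <- which(!is.na(tr$lig_r) & tr$side_r == "out")

  gen_at <- function(t) {
    ext <- external_concentrations(protocol, conditions, t)[1, ]
    kf <- kf_v; kr <- kr_v
    if (length(ext_f) > 0) kf[ext_f] <- kf[ext_f] * ext[tr$lig_f[ext_f]]
    if (length(ext_r) > 0) kr[ext_r] <- kr[ext_r] * ext[tr$lig_r[ext_r]]
    Q <- matrix(0, n, n)
    Q[cbind(jj, ii)] <- kf
    Q[cbind(ii, jj)] <- kr
    diag(Q) <- diag(Q) - colSums(Q)
    Q
  }
  deriv <- function(t, p, parms) list(as.numeric(gen_at(t) %*% p))
  # the master equation is linear: the generator is the exact Jacobian,
  # which keeps the stiff (BDF) integrator on large steps
  jac <- function(t, p, parms) gen_at(t)

  bounds <- sort(unique(c(t_grid[1],
                          unlist(lapply(protocol$segments, function(s)
                            c(s$t_start, s$t_end))))))
  bounds <- bounds[bounds >= t_grid[1] & bounds < max(t_grid)]
  bounds <- c(bounds, max(t_grid))

  out_t <- numeric(0)
  out_p <- matrix(numeric(0), ncol = n)
  y <- as.numeric(p0)
  for (k in seq_len(length(bounds) - 1)) {
    tt <- sort(unique(c(bounds[k],
                        t_grid[t_grid > bounds[k] & t_grid <= bounds[k + 1]],
                        bounds[k + 1])))
    tt <- tt[c(TRUE, diff(tt) > 1e-9)]  # lsoda rejects near-coincident times
    if (length(tt) < 2) next
    sol <- deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        method = "lsoda", rtol = 1e-8, atol = 1e-10,
                        maxsteps = 5e5, hmax = 0.25)
    if (attr(sol, "istate")[1] < 0) {
      stop("master-equation integration failed (lsoda istate = ",
           attr(sol, "istate")[1], ") on [", bounds[k], ", ",
           bounds[k + 1], "] s")
    }
    keep <- sol[, 1] %in% t_grid
    out_t <- c(out_t, sol[keep, 1])
    out_p <- rbind(out_p, sol[keep, -1, drop = FALSE])
    y <- as.numeric(sol[nrow(sol), -1])
  }
  dup <- duplicated(out_t)
  out_t <- out_t[!dup]
  out_p <- out_p[!dup, , drop = FALSE]

  drift <- max(abs(rowSums(out_p) - 1))
  if (drift > 1e-6) {
    stop("occupancy conservation drift ", format(drift),
         " exceeds 1e-6; integration unreliable")
  }
  traj <- tibble::as_tibble(as.data.frame(out_p, optional = TRUE))
  names(traj) <- nm
  traj <- dplyr::bind_cols(tibble::tibble(time = out_t), traj)
  class(traj) <- c("occupancy_trajectory", class(traj))
  attr(traj, "context") <- list(scheme = scheme, conditions = conditions,
                                protocol = protocol, constants = constants)
  traj
}

# retrieve the simulation context attached to a trajectory
traj_context <- function(traj) {
  ctx <- attr(traj, "context")
  if (is.null(ctx)) stop("trajectory carries no simulation context")
  ctx
}

#' Reshape an occupancy trajectory to long (tidy) format
#'
#' @param traj An `occupancy_trajectory` tibble from
#'   [integrate_occupancies()].
#' @return Tibble with columns `time`, `state`, `occupancy`.
#' @export
occupancy_long <- function(traj) {
  tidyr::pivot_longer(tibble::as_tibble(traj), -"time",
                      names_to = "state", values_to = "occupancy")
}
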