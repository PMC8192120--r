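#' Gibbs free-energy change of a single transition
#'
#' `dG = -RT * log(k_fwd_eff / k_rev_eff)`, where the effective rates
#' include the voltage factors and the pseudo-first-order ligand
#' concentrations of the given conditions (standard state 1 M). The
#' ligand chemical potential therefore enters through the mass-action
#' rates, which makes the closed-loop identities exact. A zero rate in
#' either direction (e.g. a ligand at zero concentration on the rebinding
#' side) yields an infinite dG, which is flagged as an error rather than
#' silently returned.
#'
#' @inheritParams build_generator
#' @param from,to State names of an existing transition (either order; the
#'   returned dG is for the `from -> to` direction).
#' @return Free-energy change in J mol^-1.
#' @examples
#' s <- two_state_scheme(20, 2)
#' step_delta_g(s, ion_conditions(), 0, "A", "B") # -RT log(10)
#' @export
step_delta_g <- function(scheme, conditions, V, from, to,
                         constants = phys_constants()) {
  tr <- scheme$transitions
  idx <- which(tr$from == from & tr$to == to)
  flip <- FALSE
  if (length(idx) == 0) {
    idx <- which(tr$from == to & tr$to == from)
    flip <- TRUE
  }
  if (length(idx) != 1) stop("no transition between ", from, " and ", to)
  r <- edge_rates(scheme, conditions, V, constants)
  kf <- r$fwd[idx]
  kr <- r$rev[idx]
  if (flip) { tmp <- kf; kf <- kr; kr <- tmp }
  if (kf <= 0 || kr <= 0) {
    stop("zero effective rate on ", from, " -> ", to,
         " under these conditions: dG is infinite")
  }
  -constants$R * constants$T * log(kf / kr)
}

#' Free-energy profile along a path of states
#'
#' Walks an ordered list of states (a path or closed loop through existing
#' transitions) and accumulates per-step and cumulative Gibbs free-energy
#' changes under the given conditions and voltage. For a closed loop the
#' total equals `-RT log` of the product of effective rate ratios around
#' the loop, i.e. the net chemiosmotic driving energy (ion gradients plus
#' `sum(zQ) * F * V`); it is zero at equilibrium conditions.
#'
#' @inheritParams step_delta_g
#' @param path Character vector of state names; consecutive entries must
#'   be joined by a transition. Repeat the first state at the end to close
#'   a loop.
#' @return A tibble of class `energy_profile`: columns `from`, `to`,
#'   `delta_g` (J mol^-1), `cumulative` (J mol^-1); attributes `V`,
#'   `total` and `zQ_sum` (sum of signed equivalent charges along the
#'   path).
#' @export
loop_profile <- function(scheme, conditions, V, path,
                         constants = phys_constants()) {
  stopifnot(length(path) >= 2)
  tr <- scheme$transitions
  steps <- purrr::map(seq_len(length(path) - 1), function(k) {
    from <- path[k]; to <- path[k + 1]
    idx <- which(tr$from == from & tr$to == to)
    sgn <- 1
    if (length(idx) == 0) {
      idx <- which(tr$from == to & tr$to == from)
      sgn <- -1
    }
    if (length(idx) != 1) {
      stop("path uses a nonexistent edge: ", from, " -> ", to)
    }
    tibble::tibble(
      from = from, to = to,
      delta_g = step_delta_g(scheme, conditions, V, from, to, constants),
      zQ = sgn * tr$zQ[idx]
    )
  })
  out <- dplyr::bind_rows(steps)
  out$cumulative <- cumsum(out$delta_g)
  res <- tibble::as_tibble(out)
  class(res) <- c("energy_profile", class(res))
  attr(res, "V") <- V
  attr(res, "total") <- sum(out$delta_g)
  attr(res, "zQ_sum") <- sum(out$zQ)
  res
}

#' Canonical loops of the shipped transporter models
#'
#' `"outer"` is the substrate-translocating loop that visits the
#' K+-loaded return limb: for DAT/NET the conformational trajectory taken
#' in the presence of intracellular K+ (through `TiClK`, `ToccClK`,
#' `ToccCl`); for SERT the K+ antiport cycle (through `TiClK`, `ToClK`).
#' `"inner"` is the loop through the direct (K+-free) return.
#'
#' @param model A `transporter_model`.
#' @param loop `"outer"` or `"inner"`.
#' @return Character vector of state names (closed: first = last).
#' @export
model_loop_path <- function(model, loop = c("outer", "inner")) {
  loop <- match.arg(loop)
  core <- if (model$id %in% c("DAT", "NET")) {
    c("ToCl", "ToClNa", "ToClNaS", "ToccClNaS", "TiClNaS", "TiClS", "TiCl")
  } else {
    c("ToCl", "ToClNa", "ToClNaS", "TiClNaS", "TiClS", "TiCl")
  }
  if (model$id %in% c("DAT", "NET")) {
    ret <- if (loop == "outer") c("TiClK", "ToccClK", "ToccCl") else "ToccCl"
  } else {
    ret <- if (loop == "outer") c("TiClK", "ToClK") else character(0)
  }
  c(core, ret, "ToCl")
}

#' Construct equilibrium ion conditions for thermodynamic checks
#'
#' All species concentrations are equalized across the membrane (at the
#' given values), which together with V = 0 collapses every driving force;
#' all loop totals are then zero for a thermodynamically consistent
#' scheme.
#'
#' @param Na,K,Cl,H,Li,S Common concentrations (M) used on both sides.
#' @return An [ion_conditions()] object.
#' @export
equilibrium_conditions <- function(Na = 0.1, K = 0.1, Cl = 0.1,
                                   H = 1e-7, Li = 0.01, S = 30e-6) {
  both <- c(Na = Na, K = K, Cl = Cl, H = H, Li = Li, S = S)
  ion_conditions(inside = both, outside = both)
}
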