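#' @name transporter_models
#' @title Calibrated kinetic models of DAT, NET and SERT
#'
#' @description
#' The three monoamine transporters are represented as alternating-access
#' cycles sharing a common core: Na+ and substrate bind to the outward-open,
#' Cl-bound transporter, the loaded carrier translocates, Na+ and then
#' substrate are released intracellularly, and the empty carrier returns to
#' the outward-facing conformation. The models differ in how intracellular
#' K+ is handled on the return limb:
#'
#' * **DAT / NET** bind K+ at the inward-open state (electrogenic), but the
#'   binding site loses affinity on the trajectory to the occluded state
#'   (`TiClK -> ToccClK`), so K+ is shed back into the cytosol
#'   (`ToccClK -> ToccCl`) before the electrogenic return step. K+ is
#'   therefore never antiported, and the +1 equivalent charge of the return
#'   step makes uptake voltage-dependent. NET shares the DAT topology and
#'   all core parameters; only its substrate binding/unbinding kinetics are
#'   slower, which accounts for its much smaller turnover.
#' * **SERT** keeps K+ bound through the return step (electroneutral,
#'   `TiClK -> ToClK`) and releases it extracellularly: genuine K+ antiport,
#'   which cancels the charge of the return limb and makes uptake largely
#'   voltage-independent. An alternative branch antiports a proton, which
#'   sustains (slower) cycling when intracellular K+ is absent. Na+
#'   competes with K+ for the same inward-facing cation site and can carry
#'   the return step too, which is what accelerates turnover into exchange
#'   mode when internal Na+ is high; at 6 mM internal Na+ this branch is
#'   essentially unoccupied. An inert dead-end Li+ complex of the
#'   inward-facing state is available behind a variant flag.
#'
#' A channel-like conducting state (`Tcond`), in equilibrium with the
#' K+-bound inward-facing conformation, carries the uncoupled current
#' component; it is enabled by default in DAT and SERT and disabled in NET.
#'
#' Base rate constants were calibrated (see the package vignette) so that
#' the shipped defaults reproduce the measured turnover and uptake
#' voltage-dependence of the three transporters, under the constraint that
#' every reaction loop is thermodynamically consistent: around each
#' independent cycle the product of forward/reverse base-rate ratios is 1,
#' so that all net driving comes from ion gradients and voltage. One
#' dependent rate per cycle enforces this exactly.
#'
#' DAT and NET substrate sites are symmetric (same kon/koff on both
#' faces), so substrate parameters drop out of the consistency constraints
#' and the two cores remain parameter-identical. The SERT serotonin site
#' is asymmetric -- extracellular dissociation is an order of magnitude
#' faster than intracellular -- which is what lets substrate-loaded
#' carriers slip backwards rapidly in exchange mode.
NULL

# ---- calibrated parameter sets -------------------------------------------
# Frozen output of the calibration run (scratch/calibrate.R); rates in s^-1
# or M^-1 s^-1, zQ in elementary charges (inward-positive, forward
# direction).

dat_core_defaults <- function() {
  list(
    kon_Na_out = 1e6, koff_Na_out = 1.5e4, zQ_Na_bind = 0.1,
    k_olf = 300, k_olr = 2400, zQ_occl_S = 0.1661,
    k_tf = 600, k_tr = 300, zQ_transloc = 0,
    koff_Na_in = 1e3, kon_Na_in = 1e4, zQ_Na_rel = 0.25,
    k_occf = 4.7181, k_occr = 10,
    k_retf = 40, zQ_ret = 1,
    kon_K_in = 1e4, koff_K_in = 3e3, zQ_K_bind = -0.25,
    k_okf = 2.6615, k_okr = 5,
    koff_K_occ = 5e3,
    k_cf = 0.07, k_cr = 1e4
  )
}

sert_core_defaults <- function() {
  list(
    kon_Na_out = 1e6, koff_Na_out = 1.5e4, zQ_Na_bind = 0,
    k_tf = 600, k_tr = 300, zQ_transloc = 0,
    koff_Na_in = 1e3, kon_Na_in = 2e4, zQ_Na_rel = 0.4517,
    k_eretf = 0.05, zQ_ret = 1,
    kon_K_in = 1e4, koff_K_in = 300, zQ_K_bind = -0.4517,
    k_kretf = 1.9580, k_kretr = 2.5, zQ_K_out = -0.5483,
    koff_K_out = 1e4,
    kon_H_in = 1e10, koff_H_in = 1e3, zQ_H_bind = -0.4517,
    k_hretf = 2.2895, k_hretr = 130, zQ_H_out = -0.5483,
    koff_H_out = 1e4,
    kon_Li_in = 1e4, koff_Li_in = 1e3, zQ_Li_bind = -0.4517,
    kon_Na2_in = 1e3, koff_Na2_in = 1e3, k_naretf = 25,
    k_cf = 0.05, k_cr = 1e4
  )
}

# per-substrate binding kinetics. APP+ values are the fluorescent-substrate
# constants and use a symmetric site; cognate values are calibrated, and the
# SERT serotonin site is asymmetric (fast extracellular dissociation), which
# is what lets high internal Na+ drive rapid exchange. kon_in/koff_in
# default to the outward-face values when not given.
substrate_kinetics <- function(transporter, substrate) {
  tab <- list(
    DAT = list(APP = list(kon = 9e5, koff = 30, k_tf = 1.8107),
               cognate = list(kon = 5e6, koff = 100, k_tf = 600)),
    NET = list(APP = list(kon = 3e5, koff = 1, k_tf = 1.8107),
               cognate = list(kon = 8e5, koff = 0.098883, k_tf = 600)),
    SERT = list(APP = list(kon = 1e5, koff = 1),
                cognate = list(kon = 5e6, koff = 1000,
                               kon_in = 5e6, koff_in = 50))
  )
  k <- tab[[transporter]][[substrate]]
  if (is.null(k)) stop("unknown substrate '", substrate, "' for ", transporter)
  if (is.null(k$kon_in)) k$kon_in <- k$kon
  if (is.null(k$koff_in)) k$koff_in <- k$koff
  k
}

# substrate-edge equivalent charges (part of the substrate parameter block,
# so DAT and NET may differ here as well as in the rates)
substrate_charges <- function(transporter) {
  switch(transporter,
    DAT = list(zQ_S_bind = 0.05, zQ_S_rel = 0.1),
    NET = list(zQ_S_bind = 0.25, zQ_S_rel = 0.4260),
    SERT = list(zQ_S_bind = 0.3983, zQ_S_rel = 0.15)
  )
}

# advanced overrides: substrate rates (sub_kon, sub_koff) and substrate-edge
# charges (zQ_S_bind, zQ_S_rel) may be supplied through `params`
sub_with_overrides <- function(sub, params) {
  if (!is.null(params$sub_kon)) sub$kon <- sub$kon_in <- params$sub_kon
  if (!is.null(params$sub_koff)) sub$koff <- sub$koff_in <- params$sub_koff
  if (!is.null(params$sub_kon_in)) sub$kon_in <- params$sub_kon_in
  if (!is.null(params$sub_koff_in)) sub$koff_in <- params$sub_koff_in
  if (!is.null(params$sub_k_tf)) sub$k_tf <- params$sub_k_tf
  sub
}
subz_with_overrides <- function(subz, params) {
  keep <- intersect(names(params), c("zQ_S_bind", "zQ_S_rel"))
  utils::modifyList(subz, params[keep])
}

# ---- scheme assembly ------------------------------------------------------

lig <- function(n) stats::setNames(as.integer(unlist(n)), names(n))

build_datnet_scheme <- function(id, sub, subz, p, with_conducting_state) {
  # translocation of the loaded carrier is substrate-specific (bulky
  # substrates translocate slowly); its fwd/rev ratio is fixed by the core
  # so every substrate instance shares the same thermodynamic closure
  if (!is.null(sub$k_tf)) {
    p$k_tr <- sub$k_tf * p$k_tr / p$k_tf
    p$k_tf <- sub$k_tf
  }
  # thermodynamic closures:
  # cycle A (transport loop; the substrate-site asymmetry factor is 1 for a
  # symmetric site):
  #   (konNa/koffNa_out)(konS/koffS)(ktf/ktr)(koffNa_in/konNa_in)
  #     (koffS_in/konS_in)(koccf/koccr)(kretf/kretr) = 1
  k_retr <- p$k_retf * (p$kon_Na_out / p$koff_Na_out) *
    (p$k_olf / p$k_olr) * (p$k_tf / p$k_tr) *
    (p$koff_Na_in / p$kon_Na_in) * (p$k_occf / p$k_occr) *
    (sub$kon * sub$koff_in) / (sub$koff * sub$kon_in)
  # cycle B (K+ detour vs direct occlusion):
  #   (konK/koffK)(kokf/kokr)(koffKocc/konKocc)(koccr/koccf) = 1
  kon_K_occ <- p$koff_K_occ * (p$kon_K_in / p$koff_K_in) *
    (p$k_okf / p$k_okr) * (p$k_occr / p$k_occf)

  states <- tibble::tribble(
    ~name, ~conformation, ~ligands,
    "ToCl", "outward", lig(c(Cl = 1)),
    "ToClNa", "outward", lig(c(Cl = 1, Na = 1)),
    "ToClNaS", "outward", lig(c(Cl = 1, Na = 1, S = 1)),
    "ToccClNaS", "occluded", lig(c(Cl = 1, Na = 1, S = 1)),
    "TiClNaS", "inward", lig(c(Cl = 1, Na = 1, S = 1)),
    "TiClS", "inward", lig(c(Cl = 1, S = 1)),
    "TiCl", "inward", lig(c(Cl = 1)),
    "TiClK", "inward", lig(c(Cl = 1, K = 1)),
    "ToccClK", "occluded", lig(c(Cl = 1, K = 1)),
    "ToccCl", "occluded", lig(c(Cl = 1))
  )
  transitions <- tibble::tribble(
    ~from, ~to, ~kf0, ~kr0, ~zQ, ~lig_f, ~side_f, ~lig_r, ~side_r,
    "ToCl", "ToClNa", p$kon_Na_out, p$koff_Na_out, p$zQ_Na_bind, "Na", "out", NA, NA,
    "ToClNa", "ToClNaS", sub$kon, sub$koff, subz$zQ_S_bind, "S", "out", NA, NA,
    "ToClNaS", "ToccClNaS", p$k_olf, p$k_olr, p$zQ_occl_S, NA, NA, NA, NA,
    "ToccClNaS", "TiClNaS", p$k_tf, p$k_tr, p$zQ_transloc, NA, NA, NA, NA,
    "TiClNaS", "TiClS", p$koff_Na_in, p$kon_Na_in, p$zQ_Na_rel, NA, NA, "Na", "in",
    "TiClS", "TiCl", sub$koff_in, sub$kon_in, subz$zQ_S_rel, NA, NA, "S", "in",
    "TiCl", "ToccCl", p$k_occf, p$k_occr, 0, NA, NA, NA, NA,
    "TiCl", "TiClK", p$kon_K_in, p$koff_K_in, p$zQ_K_bind, "K", "in", NA, NA,
    "TiClK", "ToccClK", p$k_okf, p$k_okr, 0, NA, NA, NA, NA,
    "ToccClK", "ToccCl", p$koff_K_occ, kon_K_occ, -p$zQ_K_bind, NA, NA, "K", "in",
    "ToccCl", "ToCl", p$k_retf, k_retr, p$zQ_ret, NA, NA, NA, NA
  )
  if (with_conducting_state) {
    states <- dplyr::bind_rows(states, tibble::tibble(
      name = "Tcond", conformation = "conducting",
      ligands = list(lig(c(Cl = 1, K = 1)))))
    transitions <- dplyr::bind_rows(transitions, tibble::tibble(
      from = "TiClK", to = "Tcond", kf0 = p$k_cf, kr0 = p$k_cr, zQ = 0,
      lig_f = NA_character_, side_f = NA_character_,
      lig_r = NA_character_, side_r = NA_character_))
  }
  kinetic_scheme(states, transitions, meta = list(
    transporter = id,
    substrate_bound_in = "TiClS",
    substrate_free_in = "TiCl",
    substrate_koff_in = sub$koff_in,
    substrate_kon_in = sub$kon_in,
    conducting_state = if (with_conducting_state) "Tcond" else NA
  ))
}

build_sert_scheme <- function(sub, subz, p, with_conducting_state,
                              with_proton_branch, with_li_deadend) {
  # cycle A (transport loop via the empty electrogenic return)
  k_eretr <- p$k_eretf * (p$kon_Na_out / p$koff_Na_out) * (p$k_tf / p$k_tr) *
    (p$koff_Na_in / p$kon_Na_in) *
    (sub$kon * sub$koff_in) / (sub$koff * sub$kon_in)
  # cycle B (K+ antiport return vs empty return)
  kon_K_out <- p$koff_K_out * (p$kon_K_in / p$koff_K_in) *
    (p$k_kretf / p$k_kretr) * (k_eretr / p$k_eretf)
  # cycle C (H+ antiport return vs empty return)
  kon_H_out <- p$koff_H_out * (p$kon_H_in / p$koff_H_in) *
    (p$k_hretf / p$k_hretr) * (k_eretr / p$k_eretf)
  # cycle D (Na+-bound return vs empty return): Na+ and K+ compete for the
  # same inward-facing cation site, so high internal Na+ can substitute for
  # K+ on the return step -- the exchange-mode pathway. At physiological
  # (low) internal Na+ the branch is nearly unoccupied and its reverse (a
  # Na+ leak) is kept small by the closure.
  k_naretr <- p$k_naretf * (p$kon_Na2_in / p$koff_Na2_in) *
    (p$koff_Na_out / p$kon_Na_out) * (k_eretr / p$k_eretf)

  states <- tibble::tribble(
    ~name, ~conformation, ~ligands,
    "ToCl", "outward", lig(c(Cl = 1)),
    "ToClNa", "outward", lig(c(Cl = 1, Na = 1)),
    "ToClNaS", "outward", lig(c(Cl = 1, Na = 1, S = 1)),
    "TiClNaS", "inward", lig(c(Cl = 1, Na = 1, S = 1)),
    "TiClS", "inward", lig(c(Cl = 1, S = 1)),
    "TiCl", "inward", lig(c(Cl = 1)),
    "TiClK", "inward", lig(c(Cl = 1, K = 1)),
    "ToClK", "outward", lig(c(Cl = 1, K = 1)),
    "TiClNa", "inward", lig(c(Cl = 1, Na = 1))
  )
  transitions <- tibble::tribble(
    ~from, ~to, ~kf0, ~kr0, ~zQ, ~lig_f, ~side_f, ~lig_r, ~side_r,
    "ToCl", "ToClNa", p$kon_Na_out, p$koff_Na_out, p$zQ_Na_bind, "Na", "out", NA, NA,
    "ToClNa", "ToClNaS", sub$kon, sub$koff, subz$zQ_S_bind, "S", "out", NA, NA,
    "ToClNaS", "TiClNaS", p$k_tf, p$k_tr, p$zQ_transloc, NA, NA, NA, NA,
    "TiClNaS", "TiClS", p$koff_Na_in, p$kon_Na_in, p$zQ_Na_rel, NA, NA, "Na", "in",
    "TiClS", "TiCl", sub$koff_in, sub$kon_in, subz$zQ_S_rel, NA, NA, "S", "in",
    "TiCl", "ToCl", p$k_eretf, k_eretr, p$zQ_ret, NA, NA, NA, NA,
    "TiCl", "TiClK", p$kon_K_in, p$koff_K_in, p$zQ_K_bind, "K", "in", NA, NA,
    "TiClK", "ToClK", p$k_kretf, p$k_kretr, 0, NA, NA, NA, NA,
    "ToClK", "ToCl", p$koff_K_out, kon_K_out, p$zQ_K_out, NA, NA, "K", "out",
    "TiCl", "TiClNa", p$kon_Na2_in, p$koff_Na2_in, p$zQ_K_bind, "Na", "in", NA, NA,
    "TiClNa", "ToClNa", p$k_naretf, k_naretr, 0, NA, NA, NA, NA
  )
  if (with_proton_branch) {
    states <- dplyr::bind_rows(states, tibble::tibble(
      name = c("TiClH", "ToClH"), conformation = c("inward", "outward"),
      ligands = list(lig(c(Cl = 1, H = 1)), lig(c(Cl = 1, H = 1)))))
    transitions <- dplyr::bind_rows(transitions, tibble::tribble(
      ~from, ~to, ~kf0, ~kr0, ~zQ, ~lig_f, ~side_f, ~lig_r, ~side_r,
      "TiCl", "TiClH", p$kon_H_in, p$koff_H_in, p$zQ_H_bind, "H", "in", NA, NA,
      "TiClH", "ToClH", p$k_hretf, p$k_hretr, 0, NA, NA, NA, NA,
      "ToClH", "ToCl", p$koff_H_out, kon_H_out, p$zQ_H_out, NA, NA, "H", "out"))
  }
  if (with_li_deadend) {
    states <- dplyr::bind_rows(states, tibble::tibble(
      name = "TiClLi", conformation = "inward",
      ligands = list(lig(c(Cl = 1, Li = 1)))))
    transitions <- dplyr::bind_rows(transitions, tibble::tibble(
      from = "TiCl", to = "TiClLi", kf0 = p$kon_Li_in, kr0 = p$koff_Li_in,
      zQ = p$zQ_Li_bind, lig_f = "Li", side_f = "in",
      lig_r = NA_character_, side_r = NA_character_))
  }
  if (with_conducting_state) {
    states <- dplyr::bind_rows(states, tibble::tibble(
      name = "Tcond", conformation = "conducting",
      ligands = list(lig(c(Cl = 1, K = 1)))))
    transitions <- dplyr::bind_rows(transitions, tibble::tibble(
      from = "TiClK", to = "Tcond", kf0 = p$k_cf, kr0 = p$k_cr, zQ = 0,
      lig_f = NA_character_, side_f = NA_character_,
      lig_r = NA_character_, side_r = NA_character_))
  }
  kinetic_scheme(states, transitions, meta = list(
    transporter = "SERT",
    substrate_bound_in = "TiClS",
    substrate_free_in = "TiCl",
    substrate_koff_in = sub$koff_in,
    substrate_kon_in = sub$kon_in,
    conducting_state = if (with_conducting_state) "Tcond" else NA
  ))
}

new_transporter_model <- function(id, scheme, substrate, flags, params, sub) {
  structure(list(id = id, scheme = scheme, substrate = substrate,
                 flags = flags, params = params,
                 substrate_kinetics = sub),
            class = "transporter_model")
}

#' @export
print.transporter_model <- function(x, ...) {
  cat("<transporter_model> ", x$id, " (substrate: ", x$substrate, "); ",
      nrow(x$scheme$states), " states\n", sep = "")
  invisible(x)
}

#' @rdname transporter_models
#' @param substrate `"APP"` for the fluorescent substrate APP+ or
#'   `"cognate"` for the endogenous neurotransmitter (dopamine,
#'   norepinephrine, serotonin respectively). APP+ kinetics are fixed at
#'   the published values (DAT 9e5 / 30, NET 3e5 / 1, SERT 1e5 / 1 in
#'   M^-1 s^-1 and s^-1); cognate kinetics are calibrated.
#' @param with_conducting_state Attach the channel-like `Tcond` state
#'   (default `TRUE` for DAT and SERT, `FALSE` for NET).
#' @param params Optional named list overriding individual core rate
#'   parameters (advanced use; thermodynamic closures are re-solved).
#' @return A `transporter_model` object: list with elements `id`, `scheme`
#'   (a [kinetic_scheme()]), `substrate`, `flags`, `params`.
#' @examples
#' m <- build_dat_model()
#' validate_scheme(m$scheme)
#' @export
build_dat_model <- function(substrate = c("APP", "cognate"),
                            with_conducting_state = TRUE, params = list()) {
  substrate <- match.arg(substrate)
  p <- utils::modifyList(dat_core_defaults(), params)
  sub <- sub_with_overrides(substrate_kinetics("DAT", substrate), params)
  subz <- subz_with_overrides(substrate_charges("DAT"), params)
  scheme <- build_datnet_scheme("DAT", sub, subz, p,
                                with_conducting_state)
  new_transporter_model("DAT", scheme, substrate,
                        list(with_conducting_state = with_conducting_state),
                        p, sub)
}

#' @rdname transporter_models
#' @export
build_net_model <- function(substrate = c("APP", "cognate"),
                            with_conducting_state = FALSE, params = list()) {
  substrate <- match.arg(substrate)
  p <- utils::modifyList(dat_core_defaults(), params)
  sub <- sub_with_overrides(substrate_kinetics("NET", substrate), params)
  subz <- subz_with_overrides(substrate_charges("NET"), params)
  scheme <- build_datnet_scheme("NET", sub, subz, p,
                                with_conducting_state)
  new_transporter_model("NET", scheme, substrate,
                        list(with_conducting_state = with_conducting_state),
                        p, sub)
}

#' @rdname transporter_models
#' @param with_proton_branch Include the alternative H+ antiport return
#'   branch (default `TRUE`).
#' @param with_li_deadend Include the inert intracellular Li+ dead-end
#'   complex (default `FALSE`).
#' @export
build_sert_model <- function(substrate = c("APP", "cognate"),
                             with_conducting_state = TRUE,
                             with_proton_branch = TRUE,
                             with_li_deadend = FALSE, params = list()) {
  substrate <- match.arg(substrate)
  p <- utils::modifyList(sert_core_defaults(), params)
  sub <- sub_with_overrides(substrate_kinetics("SERT", substrate), params)
  subz <- subz_with_overrides(substrate_charges("SERT"), params)
  scheme <- build_sert_scheme(sub, subz, p,
                              with_conducting_state, with_proton_branch,
                              with_li_deadend)
  new_transporter_model("SERT", scheme, substrate,
                        list(with_conducting_state = with_conducting_state,
                             with_proton_branch = with_proton_branch,
                             with_li_deadend = with_li_deadend),
                        p, sub)
}

#' @rdname transporter_models
#' @param id `"DAT"`, `"NET"` or `"SERT"`.
#' @param ... Passed to the specific builder.
#' @export
build_transporter_model <- function(id, ...) {
  switch(id,
         DAT = build_dat_model(...),
         NET = build_net_model(...),
         SERT = build_sert_model(...),
         stop("unknown transporter id: ", id))
}
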