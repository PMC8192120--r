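#' Intra- and extracellular ion conditions
#'
#' Concentrations (in M) of the species a scheme's transitions may couple
#' to, on each side of the membrane. Protons can be given directly or via
#' pH. Inert cations used for osmotic replacement (NMDG+) are not coupled
#' to any transition and therefore carry no explicit entry.
#'
#' @param inside,outside Named numeric vectors with any of
#'   `Na, K, Cl, H, Li, S` (M). Missing species default to 0;
#'   `H` defaults to the value implied by `pH_in` / `pH_out`.
#' @param pH_in,pH_out Used only when `H` is not given explicitly.
#' @return An object of class `ion_conditions`: a list with numeric vectors
#'   `inside` and `outside` covering all species.
#' @examples
#' ion_conditions(inside = c(K = 0.163, Na = 0.006),
#'                outside = c(Na = 0.163))
#' @export
ion_conditions <- function(inside = c(), outside = c(),
                           pH_in = 7.2, pH_out = 7.4) {
  fill <- function(x, pH) {
    v <- stats::setNames(numeric(length(LIGAND_SPECIES)), LIGAND_SPECIES)
    if (length(x) > 0) {
      bad <- setdiff(names(x), LIGAND_SPECIES)
      if (length(bad) > 0) stop("unknown species: ", paste(bad, collapse = ", "))
      v[names(x)] <- as.numeric(x)
    }
    if (!("H" %in% names(x))) v["H"] <- 10^(-pH)
    if (any(v < 0)) stop("concentrations must be non-negative")
    v
  }
  structure(list(inside = fill(inside, pH_in), outside = fill(outside, pH_out)),
            class = "ion_conditions")
}

#' @export
print.ion_conditions <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%s=%.4g", names(v), v), collapse = " ")
  cat("<ion_conditions>\n  in : ", fmt(x$inside), "\n  out: ", fmt(x$outside), "\n")
  invisible(x)
}

#' Replace one concentration in an ion-conditions object
#'
#' @param cond An [ion_conditions()] object.
#' @param species One of `Na, K, Cl, H, Li, S`.
#' @param side `"in"` or `"out"`.
#' @param value Concentration in M.
#' @return Modified `ion_conditions`.
#' @export
set_concentration <- function(cond, species, side, value) {
  stopifnot(inherits(cond, "ion_conditions"),
            species %in% LIGAND_SPECIES, side %in% c("in", "out"),
            is.finite(value), value >= 0)
  slot <- if (side == "in") "inside" else "outside"
  cond[[slot]][species] <- value
  cond
}

#' Named ion-condition presets of the whole-cell recording solutions
#'
#' The presets mirror the pipette (internal) and bath (external) solutions
#' of the patch-clamp experiments the simulator emulates. The external
#' solution is Na+-based (163 mM) in every preset; presets differ in the
#' internal cation: physiological K+ (163 mM K, 6 mM Na), NMDG+ replacement
#' of Na+ and K+, high internal Na+ (163 mM), high internal Li+ (163 mM,
#' with 6 mM Na), or NMDG+ at internal pH 5.6. Divalents and buffer
#' components are not coupled to any transition and are omitted.
#'
#' @param name One of `"physiological"`, `"NMDG_in"`, `"high_Na_in"`,
#'   `"high_Li_in"`, `"pH5.6_in"`, `"control_external"`.
#' @return An [ion_conditions()] object.
#' @examples
#' get_condition_preset("physiological")
#' @export
get_condition_preset <- function(name) {
  outside <- c(Na = 0.163, Cl = 0.163)
  switch(name,
    physiological = ion_conditions(
      inside = c(K = 0.163, Na = 0.006, Cl = 0.006), outside = outside),
    NMDG_in = ion_conditions(
      inside = c(Cl = 0.163), outside = outside),
    high_Na_in = ion_conditions(
      inside = c(Na = 0.163, Cl = 0.163), outside = outside),
    high_Li_in = ion_conditions(
      inside = c(Li = 0.163, Na = 0.006, Cl = 0.136), outside = outside),
    "pH5.6_in" = ion_conditions(
      inside = c(Cl = 0.141), outside = outside, pH_in = 5.6),
    control_external = ion_conditions(
      inside = c(), outside = outside),
    stop("unknown condition preset: ", name)
  )
}

#' @rdname get_condition_preset
#' @export
condition_preset_names <- function() {
  c("physiological", "NMDG_in", "high_Na_in", "high_Li_in",
    "pH5.6_in", "control_external")
}
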