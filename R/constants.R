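#' Physical constants used throughout the simulator
#'
#' Returns the bundle of physical constants entering the voltage scaling of
#' rate constants and the conversion of state fluxes into membrane currents.
#' Defaults correspond to room-temperature whole-cell recording conditions.
#'
#' @param F_const Faraday constant, C mol^-1.
#' @param R_const Gas constant, J K^-1 mol^-1.
#' @param T_abs Absolute temperature, K.
#' @param N_A Avogadro constant, mol^-1.
#'
#' @return A named list of class `phys_constants` with elements `F`, `R`,
#'   `T` and `NA_` (Avogadro; named with a trailing underscore to avoid the
#'   missing-value literal).
#' @examples
#' phys_constants()
#' phys_constants(T_abs = 310) # body temperature
#' @export
phys_constants <- function(F_const = 96485, R_const = 8.314, T_abs = 293,
                           N_A = 6.022e23) {
  stopifnot(is.finite(F_const), is.finite(R_const), is.finite(T_abs),
            is.finite(N_A), F_const > 0, R_const > 0, T_abs > 0, N_A > 0)
  structure(list(F = F_const, R = R_const, T = T_abs, NA_ = N_A),
            class = "phys_constants")
}

#' @export
print.phys_constants <- function(x, ...) {
  cat("Physical constants: F =", x$F, "C/mol, R =", x$R,
      "J/K/mol, T =", x$T, "K, N_A =", format(x$NA_), "/mol\n")
  invisible(x)
}

# species recognised in ion conditions and ligand couplings
LIGAND_SPECIES <- c("Na", "K", "Cl", "H", "Li", "S")
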