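# minimal single-site binding scheme: outward free state A, substrate-bound
# inward-facing state B, optional equivalent charge on the binding step.
# Annotated for the uptake observable so it doubles as the analytic oracle
# for concentration-response fitting (occupancy hyperbola, K_M = koff/kon).
binding_scheme <- function(kon = 1e6, koff = 30, zQ = 0) {
  kinetic_scheme(
    states = tibble::tibble(
      name = c("A", "B"),
      conformation = c("outward", "inward"),
      ligands = list(integer(0), c(S = 1L))
    ),
    transitions = tibble::tibble(
      from = "A", to = "B", kf0 = kon, kr0 = koff, zQ = zQ,
      lig_f = "S", side_f = "out", lig_r = NA_character_,
      side_r = NA_character_
    ),
    meta = list(substrate_bound_in = "B", substrate_free_in = "A",
                substrate_koff_in = koff, substrate_kon_in = kon)
  )
}

binding_model <- function(kon = 1e6, koff = 30, zQ = 0) {
  structure(list(id = "MINIMAL", scheme = binding_scheme(kon, koff, zQ),
                 substrate = "APP", flags = list(), params = list(),
                 substrate_kinetics = list(kon = kon, koff = koff)),
            class = "transporter_model")
}

# conditions with nothing but solvent: concentrations enter via protocols
blank_conditions <- function() ion_conditions(outside = c(), inside = c())

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
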