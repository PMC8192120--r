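#' Construct a kinetic scheme for an alternating-access transporter
#'
#' A kinetic scheme is a connected graph of conformational states joined by
#' reversible transitions. Each transition carries base forward/reverse rate
#' constants (s^-1, or M^-1 s^-1 when the direction is ligand-coupled), an
#' equivalent charge `zQ` (elementary charges moved inward during the forward
#' direction, symmetric-barrier convention), and optional ligand couplings
#' naming the species and membrane side whose concentration multiplies the
#' rate (pseudo-first-order binding).
#'
#' @param states Data frame with columns `name` (unique state identifiers),
#'   `conformation` (one of `"outward"`, `"occluded"`, `"inward"`,
#'   `"conducting"`), and optionally a list-column `ligands` of named integer
#'   vectors giving bound-ligand counts per state.
#' @param transitions Data frame with columns `from`, `to`, `kf0`, `kr0`,
#'   `zQ`, and optionally `lig_f`, `side_f`, `lig_r`, `side_r` (species in
#'   `Na, K, Cl, H, Li, S`; side `"in"` or `"out"`; `NA` when uncoupled).
#' @param meta Named list of free-form annotations. The observables layer
#'   looks up `substrate_bound_in`, `substrate_free_in`, `substrate_koff_in`,
#'   `substrate_kon_in` (uptake flux) and `conducting_state` (uncoupled
#'   current) here.
#'
#' @return An object of class `kinetic_scheme`.
#' @seealso [validate_scheme()], [build_generator()], [steady_state()]
#' @export
kinetic_scheme <- function(states, transitions, meta = list()) {
  states <- tibble::as_tibble(states)
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("name", "conformation") %in% names(states)),
            all(c("from", "to", "kf0", "kr0", "zQ") %in% names(transitions)))
  for (col in c("lig_f", "side_f", "lig_r", "side_r")) {
    if (!col %in% names(transitions)) transitions[[col]] <- NA_character_
  }
  if (!"ligands" %in% names(states)) {
    states$ligands <- rep(list(integer(0)), nrow(states))
  }
  if (anyDuplicated(states$name)) stop("state names must be unique")
  if (!all(transitions$from %in% states$name) ||
      !all(transitions$to %in% states$name)) {
    stop("transitions reference unknown states")
  }
  if (any(!is.finite(transitions$zQ))) stop("zQ must be finite")
  if (any(transitions$kf0 < 0 | transitions$kr0 < 0)) {
    stop("rate constants must be non-negative")
  }
  structure(list(states = states, transitions = transitions, meta = meta),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme>", nrow(x$states), "states,",
      nrow(x$transitions), "transitions")
  if (!is.null(x$meta$transporter)) cat(" [", x$meta$transporter, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Diagnose structural problems in a kinetic scheme
#'
#' Checks graph connectivity, duplicate edges between the same unordered
#' state pair, and consistency of declared ligand couplings with the
#' bound-ligand counts of the connected states (when counts are annotated).
#' Diagnostics are returned, never raised, so a scheme under construction
#' can be inspected incrementally.
#'
#' @param scheme A [kinetic_scheme()].
#' @return A character vector of diagnostics; empty if the scheme is valid.
#' @examples
#' s <- two_state_scheme(2, 1)
#' validate_scheme(s) # character(0)
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  out <- character(0)
  st <- scheme$states
  tr <- scheme$transitions

  # connectivity via breadth-first search on the undirected edge set
  if (nrow(st) > 1) {
    adj <- lapply(st$name, function(n) {
      unique(c(tr$to[tr$from == n], tr$from[tr$to == n]))
    })
    names(adj) <- st$name
    seen <- st$name[1]
    frontier <- seen
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) < nrow(st)) {
      out <- c(out, paste0("scheme is disconnected; unreachable states: ",
                           paste(setdiff(st$name, seen), collapse = ", ")))
    }
  }

  # duplicate edges per unordered pair
  if (nrow(tr) > 0) {
    key <- apply(cbind(tr$from, tr$to), 1, function(p) paste(sort(p), collapse = "|"))
    dup <- unique(key[duplicated(key)])
    if (length(dup) > 0) {
      out <- c(out, paste0("duplicate transition between pair(s): ",
                           paste(dup, collapse = "; ")))
    }
  }

  # ligand bookkeeping: destination counts must reflect declared couplings
  counts <- function(name) {
    lg <- st$ligands[[match(name, st$name)]]
    v <- stats::setNames(integer(length(LIGAND_SPECIES)), LIGAND_SPECIES)
    if (length(lg) > 0) v[names(lg)] <- lg
    v
  }
  annotated <- any(vapply(st$ligands, length, 1L) > 0)
  if (annotated) {
    for (i in seq_len(nrow(tr))) {
      diffv <- counts(tr$to[i]) - counts(tr$from[i])
      expect <- stats::setNames(integer(length(LIGAND_SPECIES)), LIGAND_SPECIES)
      if (!is.na(tr$lig_f[i])) expect[tr$lig_f[i]] <- expect[tr$lig_f[i]] + 1L
      if (!is.na(tr$lig_r[i])) expect[tr$lig_r[i]] <- expect[tr$lig_r[i]] - 1L
      # a coupling-free transition must conserve ligand counts; a forward
      # coupling must add exactly that species, a reverse coupling remove it
      if (!all(diffv == expect)) {
        out <- c(out, paste0("ligand-count mismatch on ", tr$from[i], " -> ",
                             tr$to[i], " (declared couplings do not match ",
                             "bound-ligand annotations)"))
      }
    }
  }
  unknown <- setdiff(stats::na.omit(c(tr$lig_f, tr$lig_r)), LIGAND_SPECIES)
  if (length(unknown) > 0) {
    out <- c(out, paste0("unknown ligand species: ", paste(unknown, collapse = ", ")))
  }
  out
}

#' Minimal two-state scheme
#'
#' Convenience constructor for the reversible two-state system used as the
#' analytic oracle of the integrator (closed-form relaxation with rate
#' `k12 + k21` towards occupancies `(k21, k12) / (k12 + k21)`).
#'
#' @param k12,k21 Forward and reverse rate constants, s^-1.
#' @param zQ Equivalent charge of the transition (default 0).
#' @return A [kinetic_scheme()] with states `A` and `B`.
#' @export
two_state_scheme <- function(k12, k21, zQ = 0) {
  kinetic_scheme(
    states = tibble::tibble(name = c("A", "B"),
                            conformation = c("outward", "inward")),
    transitions = tibble::tibble(from = "A", to = "B",
                                 kf0 = k12, kr0 = k21, zQ = zQ)
  )
}

#' Serialize a kinetic scheme to a structured text file
#'
#' Schemes round-trip losslessly through YAML, one document per model.
#'
#' @param scheme A [kinetic_scheme()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  st <- scheme$states
  doc <- list(
    states = lapply(seq_len(nrow(st)), function(i) {
      lg <- st$ligands[[i]]
      list(name = st$name[i], conformation = st$conformation[i],
           ligands = if (length(lg) > 0) as.list(lg) else NULL)
    }),
    transitions = lapply(seq_len(nrow(scheme$transitions)), function(i) {
      tr <- scheme$transitions[i, ]
      keep <- list(from = tr$from, to = tr$to, kf0 = tr$kf0, kr0 = tr$kr0,
                   zQ = tr$zQ)
      if (!is.na(tr$lig_f)) { keep$lig_f <- tr$lig_f; keep$side_f <- tr$side_f }
      if (!is.na(tr$lig_r)) { keep$lig_r <- tr$lig_r; keep$side_r <- tr$side_r }
      keep
    }),
    meta = scheme$meta
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a kinetic scheme from a structured text file
#'
#' @param path File written by [write_scheme()].
#' @return A [kinetic_scheme()].
#' @export
read_scheme <- function(path) {
  doc <- yaml::read_yaml(path)
  states <- tibble::tibble(
    name = vapply(doc$states, `[[`, "", "name"),
    conformation = vapply(doc$states, `[[`, "", "conformation"),
    ligands = lapply(doc$states, function(s) {
      if (is.null(s$ligands)) integer(0) else unlist(s$ligands)
    })
  )
  grab <- function(tr, key, default = NA) {
    if (is.null(tr[[key]])) default else tr[[key]]
  }
  transitions <- tibble::tibble(
    from = vapply(doc$transitions, `[[`, "", "from"),
    to = vapply(doc$transitions, `[[`, "", "to"),
    kf0 = vapply(doc$transitions, `[[`, 0, "kf0"),
    kr0 = vapply(doc$transitions, `[[`, 0, "kr0"),
    zQ = vapply(doc$transitions, `[[`, 0, "zQ"),
    lig_f = vapply(doc$transitions, grab, "", "lig_f", NA_character_),
    side_f = vapply(doc$transitions, grab, "", "side_f", NA_character_),
    lig_r = vapply(doc$transitions, grab, "", "lig_r", NA_character_),
    side_r = vapply(doc$transitions, grab, "", "side_r", NA_character_)
  )
  kinetic_scheme(states, transitions, meta = doc$meta)
}
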