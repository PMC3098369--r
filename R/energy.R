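# Restraint potential for the torsion-space structure calculations. Three
# non-negative terms: flat-bottom harmonic NOE distance wells (k = 10
# kcal/mol/A^2), flat-bottom ring-torsion wells that preclude non-4C1 ring
# shapes (k = 100 kcal/mol/rad^2, zero inside +/-(60 +/- 20) degrees), and a
# soft-sphere steric term between heavy atoms more than three bonds apart
# (k = 5 kcal/mol/A^2 below a 3.0 A cutoff).

R_GAS <- 0.0019872  # kcal/mol/K

#' Energy model parameters
#'
#' @param restraint_k NOE distance restraint force constant, kcal/mol/A^2.
#' @param ring_k Ring torsion restraint force constant, kcal/mol/rad^2.
#' @param steric_k Soft-sphere steric force constant, kcal/mol/A^2.
#' @param steric_cutoff Soft-sphere contact distance, angstroms.
#' @return An `energy_model` list.
#' @export
energy_model <- function(restraint_k = 10, ring_k = 100, steric_k = 5,
                         steric_cutoff = 3.0) {
  stopifnot(restraint_k > 0, ring_k > 0, steric_k > 0, steric_cutoff > 0)
  structure(list(restraint_k = restraint_k, ring_k = ring_k,
                 steric_k = steric_k, steric_cutoff = steric_cutoff),
            class = "energy_model")
}

# resolve restraint atom pairs to coordinate row indices once per topology
restraint_indices <- function(topo, restraints) {
  at <- topo$atoms
  find <- function(label, atom) {
    hit <- which(at$label == label & at$atom == atom)
    if (length(hit) != 1) {
      stop("restraint atom ", label, ":", atom, " not found in model",
           call. = FALSE)
    }
    hit
  }
  cbind(
    mapply(find, restraints$res_a, restraints$atom_a),
    mapply(find, restraints$res_b, restraints$atom_b)
  )
}

restraint_energy_xyz <- function(xyz, idx, lower, upper, k) {
  d <- sqrt(rowSums((xyz[idx[, 1], , drop = FALSE] -
                       xyz[idx[, 2], , drop = FALSE])^2))
  over <- pmax(0, d - upper)
  under <- pmax(0, lower - d)
  list(energy = sum(k * (over^2 + under^2)),
       violations = pmax(over, under),
       distances = d)
}

#' Flat-bottom NOE restraint energy of a model
#'
#' `E = sum k * max(0, d - upper)^2 + k * max(0, lower - d)^2` over the
#' restraints; the reported violation of a restraint is how far its distance
#' falls outside `[lower, upper]`.
#'
#' @param model A `glycan_model`.
#' @param restraints A restraint tibble (see [build_restraint_set()]) with
#'   columns `res_a`, `atom_a`, `res_b`, `atom_b`, `lower`, `upper` and
#'   optionally `force_constant`.
#' @return A one-row tibble with `energy` (kcal/mol) and `max_violation` (A).
#' @export
restraint_energy <- function(model, restraints) {
  topo <- model_topology(model)
  idx <- restraint_indices(topo, restraints)
  k <- if ("force_constant" %in% names(restraints)) {
    restraints$force_constant
  } else {
    10
  }
  r <- restraint_energy_xyz(model_xyz(model), idx, restraints$lower,
                            restraints$upper, k)
  tibble::tibble(energy = r$energy, max_violation = max(r$violations))
}

#' Ring-pucker restraint energy of a model
#'
#' Flat-bottom harmonic on each of the six endocyclic torsions of every
#' residue: zero while the torsion stays inside its +/-(60 +/- 20) degree
#' window (sign alternating around the ring as in a 4C1 chair), quadratic in
#' the excursion (radians) outside it.
#'
#' @param model A `glycan_model`.
#' @param ring_k Force constant, kcal/mol/rad^2.
#' @return Energy in kcal/mol.
#' @export
ring_restraint_energy <- function(model, ring_k = 100) {
  tor <- ring_pucker_torsions(model)
  excess <- ring_torsion_excess(tor$angle, tor$expected_sign)
  sum(ring_k * (excess / DEG)^2)
}

# degrees outside the +/-(60 +/- 20) window, on the side of the expected sign
ring_torsion_excess <- function(angle, expected_sign) {
  centred <- wrap_angle(angle * expected_sign)  # ideal +60 after reflection
  pmax(0, abs(centred - 60) - 20)
}

steric_energy_xyz <- function(xyz, pairs, k, cutoff) {
  d2 <- rowSums((xyz[pairs[, 1], , drop = FALSE] -
                   xyz[pairs[, 2], , drop = FALSE])^2)
  close <- d2 < cutoff^2
  if (!any(close)) return(0)
  sum(k * (cutoff - sqrt(d2[close]))^2)
}

#' Steric (soft-sphere) energy of a model
#'
#' `E = k * (c - d)^2` summed over heavy-atom pairs more than three bonds
#' apart (and in different residues; rigid intra-residue geometry contributes
#' a constant) whose separation `d` falls below the contact cutoff `c`.
#'
#' @param model A `glycan_model`.
#' @param steric_k Force constant, kcal/mol/A^2.
#' @param steric_cutoff Contact distance, angstroms.
#' @return Energy in kcal/mol.
#' @export
steric_energy <- function(model, steric_k = 5, steric_cutoff = 3.0) {
  topo <- model_topology(model)
  if (is.null(topo$steric_pairs)) {
    stop("model has no steric pair table (was it read from a file?)",
         call. = FALSE)
  }
  steric_energy_xyz(model_xyz(model), topo$steric_pairs, steric_k,
                    steric_cutoff)
}

#' Total restraint + ring + steric energy of a model
#'
#' @param model A `glycan_model`.
#' @param restraints Restraint tibble.
#' @param emodel An [energy_model()].
#' @return A one-row tibble with `energy`, `restraint_energy`, `ring_energy`,
#'   `steric_energy` (kcal/mol) and `max_violation` (A).
#' @export
total_energy <- function(model, restraints, emodel = energy_model()) {
  re <- restraint_energy(model, restraints)
  ring <- ring_restraint_energy(model, emodel$ring_k)
  st <- steric_energy(model, emodel$steric_k, emodel$steric_cutoff)
  tibble::tibble(
    energy = re$energy + ring + st,
    restraint_energy = re$energy,
    ring_energy = ring,
    steric_energy = st,
    max_violation = re$max_violation
  )
}
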