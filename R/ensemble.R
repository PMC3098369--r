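# Ensemble geometry analytics: optimal superposition RMSD, circular torsion
# statistics, hydrogen-bond detection and cross-structure torsion comparison
# tables.

circular_mean <- function(x) {
  th <- x / DEG
  wrap_angle(atan2(mean(sin(th)), mean(cos(th))) * DEG)
}

circular_sd <- function(x) {
  th <- x / DEG
  rbar <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  rbar <- min(1, rbar)
  sqrt(-2 * log(max(rbar, 1e-12))) * DEG
}

circular_abs_diff <- function(a, b) abs(wrap_angle(a - b))

# Kabsch: least-squares optimal rotation after centring, then RMSD
kabsch_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(t(a) %*% b)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  ar <- a %*% t(r)
  sqrt(mean(rowSums((ar - b)^2)))
}

select_atoms <- function(model, selection) {
  polar_h <- model$element == "H" &
    grepl("^H(O[0-9]|N)", model$atom)
  keep <- switch(
    selection,
    all = rep(TRUE, nrow(model)),
    heavy = model$element != "H",
    heavy_polar = model$element != "H" | polar_h,
    stop("unknown atom selection '", selection, "'", call. = FALSE)
  )
  model[keep, ]
}

#' All-atom RMSD after optimal superposition
#'
#' Matches atoms between the two models by residue label and atom name,
#' superposes them by the least-squares optimal rigid transform (Kabsch) and
#' returns the RMSD. Rigidly rotated or translated copies give 0 by
#' construction.
#'
#' @param model_a,model_b `glycan_model`s with matching atom identities.
#' @param selection `"heavy_polar"` (heavy atoms plus polar hydrogens, the
#'   default), `"heavy"`, or `"all"`.
#' @return RMSD in angstroms.
#' @export
superpose_rmsd <- function(model_a, model_b, selection = "heavy_polar") {
  a <- select_atoms(model_a, selection)
  b <- select_atoms(model_b, selection)
  key_a <- paste(a$label, a$atom)
  key_b <- paste(b$label, b$atom)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b)) {
    stop("atom mismatch between models after selection (",
         length(key_a), " vs ", length(key_b), " atoms)", call. = FALSE)
  }
  m <- match(key_a, key_b)
  kabsch_rmsd(as.matrix(a[, c("x", "y", "z")]),
              as.matrix(b[m, c("x", "y", "z")]))
}

#' Pairwise RMSD of every ensemble member to the top-ranked model
#'
#' @param ensemble A `conformer_ensemble` (or list of models).
#' @param selection Atom selection passed to [superpose_rmsd()].
#' @return A tibble with columns `rank` and `rmsd_to_best` (angstroms).
#' @export
ensemble_rmsd <- function(ensemble, selection = "heavy_polar") {
  models <- ensemble_models(ensemble)
  best <- models[[1]]
  tibble::tibble(
    rank = seq_along(models),
    rmsd_to_best = vapply(models, function(m) {
      superpose_rmsd(best, m, selection)
    }, numeric(1))
  )
}

#' Circular torsion statistics of an ensemble
#'
#' Per-linkage circular means and circular standard deviations
#' (`sqrt(-2 ln Rbar)`, in degrees) of the glycosidic phi/psi torsions across
#' the ensemble. For the tight distributions typical of restrained ensembles
#' the circular standard deviation coincides with the ordinary one while
#' remaining correct across the +/-180 wrap.
#'
#' @param ensemble A `conformer_ensemble` or list of `glycan_model`s.
#' @return A tibble with columns `linkage`, `type`, `donor_label`,
#'   `acceptor_label`, `phi_mean`, `phi_sd`, `psi_mean`, `psi_sd` (degrees).
#' @export
torsion_statistics <- function(ensemble) {
  models <- ensemble_models(ensemble)
  if (length(models) < 1) stop("empty ensemble", call. = FALSE)
  all <- purrr::map_dfr(models, measure_glycosidic_torsions)
  all |>
    dplyr::group_by(.data$linkage, .data$type, .data$donor_label,
                    .data$acceptor_label) |>
    dplyr::summarise(
      phi_mean = circular_mean(.data$phi), phi_sd = circular_sd(.data$phi),
      psi_mean = circular_mean(.data$psi), psi_sd = circular_sd(.data$psi),
      .groups = "drop"
    )
}

#' Detect hydrogen bonds in a model
#'
#' Geometric criteria: every hydrogen bonded to an oxygen or nitrogen
#' (donor-H distance below 1.2 angstroms) is tested against every other O/N
#' acceptor; a hydrogen bond is reported when the H...acceptor distance is at
#' most `max_h_a` and the donor-H...acceptor angle at least `min_angle`.
#'
#' @param model A `glycan_model`.
#' @param max_h_a Maximum H...acceptor distance, angstroms (default 2.5).
#' @param min_angle Minimum D-H...A angle, degrees (default 120).
#' @return A tibble sorted by distance with columns `donor_label`, `donor`,
#'   `hydrogen`, `acceptor_label`, `acceptor`, `distance`, `angle`.
#' @export
hydrogen_bonds <- function(model, max_h_a = 2.5, min_angle = 120) {
  xyz <- model_xyz(model)
  is_on <- model$element %in% c("O", "N")
  h_idx <- which(model$element == "H")
  on_idx <- which(is_on)
  if (length(h_idx) == 0 || length(on_idx) == 0) {
    return(empty_hbond_table())
  }

  out <- list()
  for (h in h_idx) {
    d_on <- sqrt(rowSums(sweep(xyz[on_idx, , drop = FALSE], 2,
                               xyz[h, ])^2))
    covalent <- which(d_on < 1.2)
    if (length(covalent) == 0) next          # carbon-bound hydrogen
    donor <- on_idx[covalent[which.min(d_on[covalent])]]
    acceptors <- setdiff(on_idx, donor)
    da <- sqrt(rowSums(sweep(xyz[acceptors, , drop = FALSE], 2, xyz[h, ])^2))
    cand <- which(da <= max_h_a)
    for (ci in cand) {
      acc <- acceptors[ci]
      ang <- bond_angle(xyz[donor, ], xyz[h, ], xyz[acc, ])
      if (ang >= min_angle) {
        out[[length(out) + 1]] <- tibble::tibble(
          donor_label = model$label[donor], donor = model$atom[donor],
          hydrogen = model$atom[h],
          acceptor_label = model$label[acc], acceptor = model$atom[acc],
          distance = da[ci], angle = ang
        )
      }
    }
  }
  if (length(out) == 0) return(empty_hbond_table())
  dplyr::arrange(dplyr::bind_rows(out), .data$distance)
}

empty_hbond_table <- function() {
  tibble::tibble(donor_label = character(), donor = character(),
                 hydrogen = character(), acceptor_label = character(),
                 acceptor = character(), distance = numeric(),
                 angle = numeric())
}

#' Circular absolute torsion differences between two structures
#'
#' Joins two torsion tables on their shared key columns and reports the
#' circular absolute difference of their `value` columns in degrees (so
#' -170 vs 170 gives 20, not 340).
#'
#' @param torsions_ref,torsions_other Data frames with identical key columns
#'   and a numeric `value` column (degrees).
#' @return A tibble with the key columns, `value_ref`, `value_other` and
#'   `abs_delta` (degrees).
#' @export
compare_structures <- function(torsions_ref, torsions_other) {
  torsions_ref <- tibble::as_tibble(torsions_ref)
  torsions_other <- tibble::as_tibble(torsions_other)
  stopifnot("value" %in% names(torsions_ref),
            "value" %in% names(torsions_other))
  keys <- intersect(setdiff(names(torsions_ref), "value"),
                    setdiff(names(torsions_other), "value"))
  if (length(keys) == 0) stop("no shared key columns", call. = FALSE)
  joined <- dplyr::inner_join(
    dplyr::rename(torsions_ref, value_ref = "value"),
    dplyr::rename(torsions_other, value_other = "value"),
    by = keys
  )
  if (nrow(joined) < nrow(torsions_other)) {
    stop("key mismatch: ", nrow(torsions_other) - nrow(joined),
         " row(s) of the comparison table have no reference entry",
         call. = FALSE)
  }
  dplyr::mutate(joined,
                abs_delta = circular_abs_diff(.data$value_other,
                                              .data$value_ref))
}
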