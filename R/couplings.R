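# Vicinal three-bond scalar couplings from model dihedrals. Ring H-C-C-H
# couplings use the generalized (substituent-corrected) Karplus equation
#   J(theta) = P1 cos^2(theta) + P2 cos(theta) + P3
#              + sum_i dchi_i * [P4 + P5 cos^2(xi_i * theta + P6 * |dchi_i|)]
# where dchi_i is the group electronegativity difference of substituent i
# relative to hydrogen and xi_i = +/-1 encodes its orientation. Amide
# 3J(HN,H2) couplings use a three-coefficient Karplus form. All coefficients
# live in an editable registry (YAML) rather than in code.

#' Karplus coefficient registry
#'
#' Loads the parameter registry used by the coupling back-calculation: the
#' generalized proton-proton Karplus coefficient sets (keyed by substitution
#' count), the group electronegativity differences relative to hydrogen, and
#' the three amide coefficients for 3J(HN,H2). The packaged defaults are the
#' standard empirical generalized-Karplus parameterisation for di-, tri- and
#' tetrasubstituted H-C-C-H fragments; edit the YAML (or pass your own path)
#' to substitute a different literature set.
#'
#' @param path Path to a registry YAML; default the packaged registry.
#' @return A list with elements `proton_proton` (coefficient sets),
#'   `group_electronegativity` and `amide`.
#' @export
karplus_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "karplus_registry.yaml", package = "gagnmr")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("Karplus registry file not found", call. = FALSE)
  }
  reg <- yaml::read_yaml(path)
  stopifnot(is.list(reg$proton_proton), is.list(reg$group_electronegativity))
  reg
}

# pick the proton-proton coefficient set for a substitution count
karplus_params_for <- function(n_substituents, registry) {
  key <- switch(as.character(max(2, min(4, n_substituents))),
                "2" = "disubstituted", "3" = "trisubstituted",
                "4" = "tetrasubstituted")
  p <- registry$proton_proton[[key]]
  if (is.null(p)) stop("registry has no coefficient set '", key, "'",
                       call. = FALSE)
  p
}

#' Generalized Karplus equation for proton-proton couplings
#'
#' Evaluates the substituent-corrected Karplus equation. With an empty
#' substituent set it reduces to the classical three-term form
#' `P1 cos^2(theta) + P2 cos(theta) + P3`, which is symmetric in +/- theta;
#' the orientation terms `xi` break that symmetry.
#'
#' @param theta Dihedral angle(s), degrees.
#' @param params A list with elements `P1`..`P6`.
#' @param substituents Optional data frame with columns `dchi` (group
#'   electronegativity difference vs hydrogen) and `xi` (+1 or -1).
#' @return Coupling constant(s) in Hz.
#' @export
karplus_jhh <- function(theta, params, substituents = NULL) {
  stopifnot(all(c("P1", "P2", "P3") %in% names(params)))
  th <- theta / DEG
  j <- params$P1 * cos(th)^2 + params$P2 * cos(th) + params$P3
  if (!is.null(substituents) && nrow(substituents) > 0) {
    stopifnot(all(c("dchi", "xi") %in% names(substituents)),
              all(abs(substituents$xi) == 1),
              all(c("P4", "P5", "P6") %in% names(params)))
    for (i in seq_len(nrow(substituents))) {
      dchi <- substituents$dchi[i]
      xi <- substituents$xi[i]
      j <- j + dchi *
        (params$P4 +
           params$P5 * cos((xi * theta + params$P6 * abs(dchi)) / DEG)^2)
    }
  }
  j
}

#' Amide Karplus equation for 3J(HN,H2)
#'
#' Three-coefficient Karplus form `A cos^2(theta) + B cos(theta) + C` for the
#' acetamido H2-C2-N-HN dihedral; trans (theta near 180 degrees) gives the
#' large 8-10 Hz regime observed for GalNAc amides.
#'
#' @param theta Dihedral angle(s), degrees.
#' @param coefficients A list with elements `A`, `B`, `C`; default the
#'   registry's `amide` entry.
#' @return Coupling constant(s) in Hz.
#' @export
karplus_jnh <- function(theta, coefficients = karplus_registry()$amide) {
  if (is.null(coefficients) ||
      !all(c("A", "B", "C") %in% names(coefficients))) {
    stop("amide Karplus coefficients are not configured ",
         "(registry entry 'amide' with A, B, C)", call. = FALSE)
  }
  th <- theta / DEG
  coefficients$A * cos(th)^2 + coefficients$B * cos(th) + coefficients$C
}

# heavy atoms bonded to `center` (geometric adjacency; catches glycosidic
# oxygens that belong to the neighbouring residue)
bonded_heavy <- function(model, center, exclude_index = integer(0)) {
  xyz <- model_xyz(model)
  d <- sqrt(colSums((t(xyz) - center)^2))
  hit <- which(d > 0.1 & d < 1.75 & model$element != "H")
  setdiff(hit, exclude_index)
}

# classify a substituent atom into a registry electronegativity group
substituent_group <- function(model, index) {
  el <- model$element[index]
  if (el == "N") return("NC")
  if (el == "C") return("CC")
  if (el == "O") {
    xyz <- model_xyz(model)
    d <- sqrt(colSums((t(xyz) - xyz[index, ])^2))
    has_h <- any(d > 0.1 & d < 1.05 & model$element == "H")
    return(if (has_h) "OH" else "OR")
  }
  "CC"
}

#' Back-calculate ring proton-proton couplings of a model
#'
#' Computes 3J for the H1-H2, H2-H3, H3-H4 and H4-H5 pairs of every residue
#' from the corresponding H-C-C-H dihedrals with the generalized Karplus
#' equation. Substituents on the two carbons are found geometrically, their
#' electronegativity groups taken from the registry, and their orientation
#' signs derived from the local dihedral geometry (+1 when the substituent
#' lies at +120 degrees from the coupled proton on the same carbon).
#'
#' @param model A `glycan_model`.
#' @param registry A [karplus_registry()].
#' @return A tibble with columns `residue`, `label`, `kind`, `pair`,
#'   `theta` (H-C-C-H dihedral, degrees) and `j_calc` (Hz).
#' @export
back_calculate_ring_couplings <- function(model,
                                          registry = karplus_registry()) {
  labels <- unique(model$label)
  purrr::map_dfr(labels, function(lab) {
    sub <- model[model$label == lab, ]
    purrr::map_dfr(1:4, function(i) {
      ha <- paste0("H", i)
      hb <- paste0("H", i + 1)
      ca <- paste0("C", i)
      cb <- paste0("C", i + 1)
      for (nm in c(ha, hb, ca, cb)) {
        if (!nm %in% sub$atom) {
          stop("missing atom ", lab, ":", nm,
               " for coupling back-calculation", call. = FALSE)
        }
      }
      p_ha <- model_atom(model, lab, ha)
      p_hb <- model_atom(model, lab, hb)
      p_ca <- model_atom(model, lab, ca)
      p_cb <- model_atom(model, lab, cb)
      theta <- measure_torsion(p_ha, p_ca, p_cb, p_hb)

      idx_ca <- which(model$label == lab & model$atom == ca)
      idx_cb <- which(model$label == lab & model$atom == cb)
      subs_a <- bonded_heavy(model, p_ca, exclude_index = idx_cb)
      subs_b <- bonded_heavy(model, p_cb, exclude_index = idx_ca)

      xi_for <- function(index, on_a) {
        s <- c(model$x[index], model$y[index], model$z[index])
        t_s <- if (on_a) {
          measure_torsion(s, p_ca, p_cb, p_hb)
        } else {
          measure_torsion(p_ha, p_ca, p_cb, s)
        }
        sign(wrap_angle(t_s - theta))
      }
      substituents <- tibble::tibble(
        index = c(subs_a, subs_b),
        on_a = rep(c(TRUE, FALSE), c(length(subs_a), length(subs_b)))
      )
      substituents$group <- vapply(substituents$index, function(ix) {
        substituent_group(model, ix)
      }, character(1))
      substituents$dchi <- vapply(substituents$group, function(g) {
        v <- registry$group_electronegativity[[g]]
        if (is.null(v)) stop("no electronegativity for group '", g, "'",
                             call. = FALSE)
        v
      }, numeric(1))
      substituents$xi <- mapply(xi_for, substituents$index, substituents$on_a)

      params <- karplus_params_for(nrow(substituents), registry)
      tibble::tibble(
        residue = sub$residue[1], label = lab, kind = sub$kind[1],
        pair = paste0(i, ",", i + 1), theta = theta,
        j_calc = karplus_jhh(theta, params, substituents)
      )
    })
  })
}

#' Back-calculate amide 3J(HN,H2) couplings of a model
#'
#' @param model A `glycan_model`.
#' @param coefficients Amide Karplus coefficients (see [karplus_jnh()]).
#' @return A tibble with columns `residue`, `label`, `theta` (H2-C2-N-HN
#'   dihedral, degrees) and `j_calc` (Hz), one row per GalNAc residue.
#' @export
back_calculate_amide_couplings <- function(model,
                                           coefficients =
                                             karplus_registry()$amide) {
  labels <- unique(model$label[model$kind == "GalNAc"])
  purrr::map_dfr(labels, function(lab) {
    theta <- measure_torsion(
      model_atom(model, lab, "H2"), model_atom(model, lab, "C2"),
      model_atom(model, lab, "N"), model_atom(model, lab, "HN")
    )
    tibble::tibble(
      residue = model$residue[model$label == lab][1], label = lab,
      theta = theta, j_calc = karplus_jnh(theta, coefficients)
    )
  })
}

#' Compare calculated and observed couplings
#'
#' Joins predictions and observations on their shared key columns and
#' reports per-pair differences and the root-mean-square difference over the
#' matched rows. Rows present on only one side are kept with `NA`
#' differences (flagged, not fatal).
#'
#' @param predictions Data frame with key columns and `j_calc` (Hz).
#' @param observations Data frame with key columns and `j_obs` (Hz).
#' @return A tibble with the key columns, `j_calc`, `j_obs`, `delta`
#'   (`j_calc - j_obs`) and `abs_delta`; the RMS difference over matched rows
#'   is attached as attribute `"rms"` (also retrievable with
#'   [coupling_rms()]).
#' @export
compare_couplings <- function(predictions, observations) {
  predictions <- tibble::as_tibble(predictions)
  observations <- tibble::as_tibble(observations)
  stopifnot("j_calc" %in% names(predictions), "j_obs" %in% names(observations))
  keys <- intersect(setdiff(names(predictions), "j_calc"),
                    setdiff(names(observations), "j_obs"))
  if (length(keys) == 0) stop("no shared key columns", call. = FALSE)
  out <- dplyr::full_join(
    dplyr::select(predictions, dplyr::all_of(c(keys, "j_calc"))),
    dplyr::select(observations, dplyr::all_of(c(keys, "j_obs"))),
    by = keys
  )
  out <- dplyr::mutate(out, delta = .data$j_calc - .data$j_obs,
                       abs_delta = abs(.data$delta))
  unmatched <- sum(is.na(out$delta))
  if (unmatched > 0) {
    message(unmatched, " row(s) without a matched counterpart (flagged n/d)")
  }
  rms <- sqrt(mean(out$delta[!is.na(out$delta)]^2))
  attr(out, "rms") <- rms
  out
}

#' @rdname compare_couplings
#' @param comparison The result of [compare_couplings()].
#' @export
coupling_rms <- function(comparison) attr(comparison, "rms")
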