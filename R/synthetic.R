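# Synthetic-data generators. Each generator is the exact inverse of the model
# its consumer assumes (NOESY intensities from I = k * r^-6, shift series from
# a straight line in temperature), so every analysis stage can be validated
# end to end without experimental input.

# evaluate `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Fixed-geometry reference proton pairs of a chondroitin chain
#'
#' Five intra-residue 1,3-diaxial proton pairs whose separation is fixed by
#' the rigid 4C1 chair (independent of the glycosidic torsions), used to
#' calibrate the NOE intensity-distance relationship.
#'
#' @return A tibble with columns `res_a`, `atom_a`, `res_b`, `atom_b`.
#' @export
cn_reference_pairs <- function() {
  tibble::tribble(
    ~res_a, ~atom_a, ~res_b, ~atom_b,
    "U2", "H1", "U2", "H3",
    "U2", "H1", "U2", "H5",
    "U2", "H3", "U2", "H5",
    "N3", "H1", "N3", "H3",
    "N3", "H1", "N3", "H5"
  )
}

#' Simulate a NOESY cross-peak table from a model structure
#'
#' Generates intensities for the five fixed-geometry reference pairs and the
#' conformationally dependent inter-residue pairs of the model with the exact
#' spin-pair relationship `I = k_true * r^-6`, optionally corrupted by
#' multiplicative lognormal noise. With `overlap_grouping = TRUE` the
#' equivalent-linkage conformational peaks are summed into class peaks
#' (residue labels `"N"` / `"U"`) carrying their multiplicity — 3 for
#' beta(1->3) pairs and 2 for beta(1->4) pairs in a hexasaccharide.
#'
#' @param model A `glycan_model`.
#' @param k_true Proportionality constant of the generator (intensity * A^6).
#' @param noise `"none"` or `"multiplicative-lognormal"`.
#' @param noise_sd Fractional standard deviation of the lognormal noise
#'   (sdlog of the multiplicative factor).
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @param overlap_grouping Merge equivalent-linkage conformational peaks.
#' @param reference_pairs Data frame of intra-residue reference pairs;
#'   defaults to [cn_reference_pairs()].
#' @return A peak tibble with columns `res_a`, `atom_a`, `res_b`, `atom_b`,
#'   `distance` (the generating truth), `intensity`, `multiplicity`, `role`.
#' @export
simulate_noesy <- function(model, k_true = 100,
                           noise = c("none", "multiplicative-lognormal"),
                           noise_sd = 0, seed = NULL,
                           overlap_grouping = FALSE,
                           reference_pairs = cn_reference_pairs()) {
  noise <- match.arg(noise)
  stopifnot(k_true > 0, noise_sd >= 0)
  topo <- model_topology(model)

  refs <- tibble::as_tibble(reference_pairs)
  refs$role <- "reference"
  refs$linkage <- NA_integer_
  refs$type <- NA_character_
  conf <- expected_conformational_noes(topo$length)
  conf$role <- "conformational"
  peaks <- dplyr::bind_rows(
    refs,
    dplyr::select(conf, "res_a", "atom_a", "res_b", "atom_b", "role",
                  "linkage", "type")
  )
  peaks$distance <- purrr::pmap_dbl(
    peaks[, c("res_a", "atom_a", "res_b", "atom_b")],
    function(res_a, atom_a, res_b, atom_b) {
      model_distance(model, res_a, atom_a, res_b, atom_b)
    }
  )
  peaks$intensity <- k_true * peaks$distance^-6
  peaks$multiplicity <- 1

  if (overlap_grouping) {
    conf_rows <- peaks$role == "conformational"
    grouped <- peaks[conf_rows, ] |>
      dplyr::group_by(.data$type, .data$atom_a, .data$atom_b) |>
      dplyr::summarise(intensity = sum(.data$intensity),
                       multiplicity = dplyr::n(),
                       distance = NA_real_, .groups = "drop") |>
      dplyr::mutate(res_a = "N", res_b = "U", role = "conformational",
                    linkage = NA_integer_)
    peaks <- dplyr::bind_rows(peaks[!conf_rows, ], grouped)
  }

  if (noise == "multiplicative-lognormal" && noise_sd > 0) {
    peaks$intensity <- with_seed(seed, {
      peaks$intensity * exp(stats::rnorm(nrow(peaks), 0, noise_sd))
    })
  }
  dplyr::select(peaks, "res_a", "atom_a", "res_b", "atom_b", "linkage",
                "type", "role", "distance", "intensity", "multiplicity")
}

#' Simulate an amide-proton shift-versus-temperature series
#'
#' Generates `delta(T) = intercept + slope_true * T / 1000 + noise`, the
#' linear temperature dependence assumed by the temperature-coefficient
#' analysis (`slope_true` in ppb per degree C, `intercept` in ppm).
#'
#' @param slope_true Temperature coefficient in ppb/degree C (negative =
#'   upfield with increasing temperature).
#' @param intercept Chemical shift at 0 degrees C, ppm.
#' @param temps Temperatures in degrees C (at least two).
#' @param noise_sd Gaussian noise standard deviation in ppm.
#' @param seed Optional integer seed.
#' @return A tibble with columns `temperature_C` and `delta_ppm`.
#' @export
simulate_shift_series <- function(slope_true, intercept = 8.4,
                                  temps = c(5, 25, 35), noise_sd = 0,
                                  seed = NULL) {
  stopifnot(length(temps) >= 2)
  delta <- intercept + slope_true * temps / 1000
  if (noise_sd > 0) {
    delta <- with_seed(seed, delta + stats::rnorm(length(temps), 0, noise_sd))
  }
  tibble::tibble(temperature_C = temps, delta_ppm = delta)
}

# ensemble mean glycosidic torsions of the hexasaccharide solution structure
CN6_CONSENSUS_TORSIONS <- tibble::tibble(
  linkage = 1:5,
  type = c("b13", "b14", "b13", "b14", "b13"),
  phi = c(-73, -73, -73, -73, -72),
  psi = c(108, -118, 107, -116, 109)
)

#' Synthetic hexasaccharide at the consensus solution-structure torsions
#'
#' Builds the chondroitin hexasaccharide with its glycosidic torsions set to
#' the ensemble-mean values of the solution structure (phi about -73 degrees
#' everywhere; psi about +108 across the beta(1->3) linkages and about -117
#' across the beta(1->4) linkages), with trans exocyclic torsions. This is a
#' synthetic stand-in for the deposited coordinates — an idealised chain, not
#' the experimental ensemble — used as ground truth for NOE simulation,
#' coupling back-calculation smoke tests and analysis round-trips.
#'
#' @return A `glycan_model` of the hexasaccharide (CN6).
#' @examples
#' fx <- reference_torsion_fixture()
#' measure_glycosidic_torsions(fx)
#' @export
reference_torsion_fixture <- function() {
  assemble_chain(6, CN6_CONSENSUS_TORSIONS[, c("phi", "psi")])
}

#' Perturb a model into a jittered pseudo-ensemble
#'
#' Returns `n` copies of the model with independent Gaussian jitter applied
#' to every glycosidic torsion — a fixture generator for RMSD and circular
#' statistics tests. Zero jitter yields identical copies.
#'
#' @param model A `glycan_model`.
#' @param torsion_jitter_sd Jitter standard deviation, degrees.
#' @param n Number of models.
#' @param seed Optional integer seed.
#' @return A `conformer_ensemble` tibble (columns `rank`, `energy`,
#'   `max_violation`, `model`); energies are `NA` (no potential evaluated).
#' @export
perturb_ensemble <- function(model, torsion_jitter_sd = 5, n = 10,
                             seed = NULL) {
  stopifnot(n >= 1, torsion_jitter_sd >= 0)
  topo <- model_topology(model)
  par <- attr(model, "par")
  n_link <- topo$length - 1
  models <- with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      p <- par
      p$phi <- p$phi + stats::rnorm(n_link, 0, torsion_jitter_sd)
      p$psi <- p$psi + stats::rnorm(n_link, 0, torsion_jitter_sd)
      new_glycan_model(topo, p)
    })
  })
  new_conformer_ensemble(
    tibble::tibble(rank = seq_len(n), round = seq_len(n),
                   energy = NA_real_, max_violation = NA_real_,
                   model = models),
    n_generated = n, kept_fraction = 1, seed = seed
  )
}
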