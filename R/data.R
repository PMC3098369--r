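# Packaged reference tables: published chemical-shift assignments, scalar
# couplings, temperature coefficients and glycosidic-torsion comparisons for
# chondroitin and hyaluronan oligosaccharides, transcribed (with n/d markers
# preserved as NA) so the table arithmetic is testable offline.

REFERENCE_TABLES <- c(
  cn4_ha4_shifts = "table_cn4_ha4_shifts.csv",
  cn4_couplings = "table_cn4_couplings.csv",
  amide_couplings = "table_amide_couplings.csv",
  temperature_coefficients = "table_temperature_coefficients.csv",
  ensemble_torsions = "table_ensemble_torsions.csv",
  torsion_comparison = "table_torsion_comparison.csv"
)

#' Packaged reference tables
#'
#' Loads one of the reference data tables shipped with the package:
#'
#' * `cn4_ha4_shifts` — 1H/13C assignments of the chondroitin and hyaluronan
#'   tetrasaccharides with the published absolute differences
#'   (`abs_printed`).
#' * `cn4_couplings` — observed 3J(H,H) ring couplings of the chondroitin
#'   tetrasaccharide, back-calculated hexasaccharide values and the
#'   chondroitin-hyaluronan differences (`diff_printed`).
#' * `amide_couplings` — observed 1J(H,N) and 3J(HN,H2) amide couplings.
#' * `temperature_coefficients` — amide shift series at 5/25/35 degrees C and
#'   the published coefficients (ppb per degree C).
#' * `ensemble_torsions` — per-linkage mean (sd) glycosidic torsions of the
#'   hexasaccharide solution ensemble.
#' * `torsion_comparison` — glycosidic torsions of published chondroitin /
#'   chondroitin-sulfate / hyaluronan structures with their printed absolute
#'   deviations from the hexasaccharide values.
#'
#' @param name One of the table names above.
#' @return A tibble.
#' @export
reference_table <- function(name = names(REFERENCE_TABLES)) {
  name <- match.arg(name)
  path <- system.file("extdata", REFERENCE_TABLES[[name]], package = "gagnmr")
  if (!nzchar(path)) stop("reference table not found: ", name, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", "n/d", "n/c"))
}
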