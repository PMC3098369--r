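# Chemical-shift table arithmetic: assignment differences between
# oligosaccharides, amide-proton temperature coefficients, hydrogen-bond
# classification from those coefficients, and the empirical sulfation shift
# offset.

#' Absolute chemical-shift differences between two assignment tables
#'
#' Joins two shift tables on their shared key columns (by default whatever
#' identifying columns both tables carry, e.g. `ring`, `reporter`, `anomer`)
#' and reports `|delta_a - delta_b|` per reporter atom. Rows with a missing
#' shift on either side are kept with `NA` (the n/d convention); keys present
#' on only one side are reported via a message.
#'
#' @param table_a,table_b Data frames with key columns and a `delta_ppm`
#'   column.
#' @return A tibble with the key columns, `delta_a`, `delta_b`, `abs_diff`.
#' @export
abs_shift_difference <- function(table_a, table_b) {
  table_a <- tibble::as_tibble(table_a)
  table_b <- tibble::as_tibble(table_b)
  stopifnot("delta_ppm" %in% names(table_a), "delta_ppm" %in% names(table_b))
  keys <- intersect(setdiff(names(table_a), "delta_ppm"),
                    setdiff(names(table_b), "delta_ppm"))
  if (length(keys) == 0) stop("no shared key columns", call. = FALSE)
  joined <- dplyr::full_join(
    dplyr::rename(table_a, delta_a = "delta_ppm"),
    dplyr::rename(table_b, delta_b = "delta_ppm"),
    by = keys
  )
  unmatched <- sum(is.na(joined$delta_a) & !is.na(joined$delta_b)) +
    sum(!is.na(joined$delta_a) & is.na(joined$delta_b))
  out <- dplyr::mutate(joined, abs_diff = abs(.data$delta_a - .data$delta_b))
  if (unmatched > 0) {
    message(unmatched, " key(s) present in only one table (abs_diff = NA)")
  }
  out
}

#' Amide-proton temperature coefficient
#'
#' Ordinary least-squares slope of chemical shift against temperature,
#' reported in ppb per degree C (negative = upfield with increasing
#' temperature), together with the fit R^2. With two points the line is
#' exact. If `series` is grouped (see [dplyr::group_by()]), one coefficient
#' is returned per group.
#'
#' @param series A data frame with columns `temperature_C` and `delta_ppm`
#'   (two or more distinct temperatures per series).
#' @return A tibble with columns `slope_ppb_per_C`, `r_squared` and `n`.
#' @export
temperature_coefficient <- function(series) {
  if (dplyr::is_grouped_df(series)) {
    return(dplyr::summarise(
      series,
      temperature_coefficient_one(.data$temperature_C, .data$delta_ppm),
      .groups = "drop"
    ))
  }
  series <- tibble::as_tibble(series)
  stopifnot(all(c("temperature_C", "delta_ppm") %in% names(series)))
  temperature_coefficient_one(series$temperature_C, series$delta_ppm)
}

temperature_coefficient_one <- function(temperature, delta) {
  keep <- !is.na(temperature) & !is.na(delta)
  temperature <- temperature[keep]
  delta <- delta[keep]
  if (length(unique(temperature)) < 2) {
    stop("need at least two distinct temperatures", call. = FALSE)
  }
  fit <- stats::lm(delta ~ temperature)
  slope_ppb <- unname(stats::coef(fit)[2]) * 1000
  ss_tot <- sum((delta - mean(delta))^2)
  r2 <- if (ss_tot < 1e-30) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  tibble::tibble(slope_ppb_per_C = slope_ppb, r_squared = r2,
                 n = length(delta))
}

FREE_EXCHANGE_COEFFICIENT <- -11  # ppb/degree C, amide protons in free exchange

#' Classify hydrogen bonding from a temperature coefficient
#'
#' Amide-proton temperature coefficients larger than 3 ppb/degree C in
#' magnitude indicate the absence of a persistent intra-molecular hydrogen
#' bond; values at or inside the boundary are consistent with one. The
#' distance of the coefficient from the free-exchange reference value
#' (about -11 ppb/degree C) is reported alongside.
#'
#' @param slope Temperature coefficient(s), ppb per degree C.
#' @return A tibble with columns `slope_ppb_per_C`, `classification`
#'   (`"persistent-hbond-consistent"` or `"no-persistent-hbond"`) and
#'   `delta_from_free_exchange` (ppb per degree C).
#' @export
classify_hbond_from_coefficient <- function(slope) {
  stopifnot(all(is.finite(slope)))
  tibble::tibble(
    slope_ppb_per_C = slope,
    classification = ifelse(abs(slope) > 3, "no-persistent-hbond",
                            "persistent-hbond-consistent"),
    delta_from_free_exchange = slope - FREE_EXCHANGE_COEFFICIENT
  )
}

#' Predict the proton shift of a sulfated position
#'
#' Applies the empirical ~0.5 ppm downfield shift of the H-4 or H-6
#' resonance upon 4-O or 6-O sulfation of a GalNAc residue.
#'
#' @param delta_unsulfated Proton shift(s) of the unsulfated position, ppm.
#' @param site `"4-O"` or `"6-O"`.
#' @return Predicted shift(s), ppm.
#' @export
predict_sulfation_shift <- function(delta_unsulfated, site = c("4-O", "6-O")) {
  site <- match.arg(site)
  delta_unsulfated + 0.5
}
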