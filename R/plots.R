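# ggplot2 graphics for the main result types.

#' Plot an NOE calibration
#'
#' Intensity against r^-6 for the reference NOEs with the fitted
#' through-origin line.
#'
#' @param object A [fit_noe_calibration()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot noe_calibration
#' @export
autoplot.noe_calibration <- function(object, ...) {
  df <- dplyr::mutate(object$references, r6 = .data$distance^-6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r6, y = .data$intensity)) +
    ggplot2::geom_abline(intercept = 0, slope = object$k,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(r^-6 ~ (ring(A)^-6)),
                  y = "NOE intensity (a.u.)",
                  title = sprintf("I = k r^-6, k = %.3g", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a conformer ensemble energy ranking
#'
#' @param object A `conformer_ensemble`.
#' @param ... Unused.
#' @return A ggplot of energy against rank, coloured by maximum restraint
#'   violation.
#' @method autoplot conformer_ensemble
#' @export
autoplot.conformer_ensemble <- function(object, ...) {
  df <- tidy.conformer_ensemble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$energy,
                                   colour = .data$max_violation)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "energy rank", y = "energy (kcal/mol)",
                  colour = "max violation (Å)") +
    ggplot2::theme_minimal()
}

#' Glycosidic torsion map of an ensemble
#'
#' phi/psi scatter per linkage type; the tight clusters of a restrained
#' ensemble show up as single spots.
#'
#' @param ensemble A `conformer_ensemble` or list of `glycan_model`s.
#' @return A ggplot faceted by linkage type.
#' @export
plot_torsion_map <- function(ensemble) {
  models <- ensemble_models(ensemble)
  df <- purrr::map_dfr(models, measure_glycosidic_torsions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$psi,
                                   colour = factor(.data$linkage))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~type) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi ~ (degree)), y = expression(psi ~ (degree)),
                  colour = "linkage") +
    ggplot2::theme_minimal()
}

#' Plot a shift-versus-temperature series
#'
#' @param series A tibble with `temperature_C` and `delta_ppm` columns.
#' @return A ggplot with the least-squares line used by
#'   [temperature_coefficient()].
#' @export
plot_shift_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$temperature_C,
                                       y = .data$delta_ppm)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "temperature (°C)", y = "δ (ppm)") +
    ggplot2::theme_minimal()
}
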