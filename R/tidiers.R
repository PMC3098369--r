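# broom-style methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an NOE calibration fit
#'
#' @param x A [fit_noe_calibration()] object.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate` and `std.error`.
#' @method tidy noe_calibration
#' @export
tidy.noe_calibration <- function(x, ...) {
  se <- if (x$n > 1) {
    sxx <- sum(x$references$distance^-12)
    sqrt((x$fit_residual / (x$n - 1)) / sxx)
  } else {
    NA_real_
  }
  tibble::tibble(term = "k", estimate = x$k, std.error = se)
}

#' @rdname tidy.noe_calibration
#' @method glance noe_calibration
#' @export
glance.noe_calibration <- function(x, ...) {
  tibble::tibble(k = x$k, fit_residual = x$fit_residual, n_references = x$n)
}

#' Tidy a conformer ensemble
#'
#' @param x A `conformer_ensemble` from [generate_ensemble()].
#' @param ... Unused.
#' @return Per-model rows (`rank`, `round`, `energy`, `max_violation`)
#'   without the model list-column.
#' @method tidy conformer_ensemble
#' @export
tidy.conformer_ensemble <- function(x, ...) {
  tibble::as_tibble(x[, setdiff(names(x), "model")])
}

#' @rdname tidy.conformer_ensemble
#' @method glance conformer_ensemble
#' @export
glance.conformer_ensemble <- function(x, ...) {
  tibble::tibble(
    n_kept = nrow(x),
    n_generated = attr(x, "n_generated"),
    kept_fraction = attr(x, "kept_fraction"),
    energy_min = min(x$energy),
    energy_max = max(x$energy),
    max_violation_best = x$max_violation[which.min(x$energy)]
  )
}
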