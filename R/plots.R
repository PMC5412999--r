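# ggplot2 quick-look methods.  Every result type is tabular, so each
# autoplot() is a thin pivot + geom layer that callers can extend.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_colour_brewer theme_minimal
NULL

ion_labels <- c(H = "H+", Na = "Na+", Cl = "Cl-", L = "phthalate (L2-)")

envelope_long <- function(x) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::starts_with("gamma_"), names_to = "ion",
                        names_prefix = "gamma_", values_to = "gamma") |>
    mutate(ion = dplyr::recode(.data$ion, !!!ion_labels))
}

#' Plot a predicted adsorption envelope
#'
#' Surface density versus pH, one curve per ion (derived Γ_H included).
#'
#' @param object An `iex_envelope` from [predict_envelope()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iex_envelope <- function(object, ...) {
  ggplot(envelope_long(object), aes(.data$pH, .data$gamma,
                                    colour = .data$ion)) +
    geom_line() +
    labs(x = "pH", y = expression(Gamma ~ (mu * mol ~ m^-2)),
         colour = NULL) +
    theme_minimal()
}

#' Plot an envelope dataset (observations)
#'
#' @param object An [envelope_dataset()].
#' @param model Optional [iex_model()]; when given, predicted curves are
#'   overlaid on the observations.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iex_dataset <- function(object, model = NULL, ...) {
  p <- ggplot(envelope_long(object),
              aes(.data$pH, .data$gamma, colour = .data$ion)) +
    geom_point(na.rm = TRUE) +
    labs(x = "pH", y = expression(Gamma ~ (mu * mol ~ m^-2)),
         colour = NULL) +
    theme_minimal()
  if (!is.null(model)) {
    pred <- predict_envelope(model, object,
                             geometry = attr(object, "geometry"))
    p <- p + geom_line(data = envelope_long(pred))
  }
  p
}

#' Plot a fitted model against its data
#'
#' Observed points and fitted curves per ion.
#'
#' @param object An `iex_fit` from [fit_pks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iex_fit <- function(object, ...) {
  res <- object$residuals |>
    mutate(ion = dplyr::recode(.data$ion, !!!ion_labels))
  ggplot(res, aes(.data$pH, colour = .data$ion)) +
    geom_point(aes(y = .data$observed), na.rm = TRUE) +
    geom_line(aes(y = .data$predicted), na.rm = TRUE) +
    labs(x = "pH", y = expression(Gamma ~ (mu * mol ~ m^-2)),
         colour = NULL) +
    theme_minimal()
}

#' Plot aqueous speciation fractions versus pH
#'
#' @param object A tibble from [speciation_profile()].
#' @param component Component whose fractions to show (default `"L"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_speciation <- function(object, component = "L", ...) {
  dat <- filter(object, .data$component == !!component)
  ggplot(dat, aes(.data$pH, .data$fraction, colour = .data$species)) +
    geom_line() +
    labs(x = "pH", y = "fraction of total", colour = NULL) +
    theme_minimal()
}
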