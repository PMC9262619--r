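## Plots -----------------------------------------------------------------------

#' Plot a two-state melting fit
#'
#' Melting curve with the fitted folded/unfolded baselines, the fitted
#' two-state signal and the melting temperature.
#'
#' @param object A `g4_two_state_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot g4_two_state_fit
#' @export
autoplot.g4_two_state_fit <- function(object, ...) {
  d <- tibble(temperature_C = object$curve$temperature_C,
              absorbance = object$curve$absorbance)
  b <- object$baselines
  d$folded <- baseline_at(b$folded, d$temperature_C)
  d$unfolded <- baseline_at(b$unfolded, d$temperature_C)
  a <- two_state_alpha(d$temperature_C, object$dH, object$Tm)
  d$fitted <- a * d$folded + (1 - a) * d$unfolded
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_C)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$absorbance),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::geom_line(ggplot2::aes(y = .data$folded),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$unfolded),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$Tm, linetype = "dotted") +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Absorbance (a.u.)",
      title = sprintf("Two-state fit: Tm = %.1f °C, ΔH° = %.1f kcal/mol",
                      object$Tm, object$dH)) +
    ggplot2::theme_minimal()
}

#' Van't Hoff plot of a fitted curve
#'
#' `ln K` against `1/T` for the points inside the fit window, with the
#' regression line implied by the fitted enthalpy and entropy.
#'
#' @param fit A `g4_two_state_fit`.
#' @return A ggplot object.
#' @export
plot_vant_hoff <- function(fit) {
  stopifnot(inherits(fit, "g4_two_state_fit"))
  a <- fit$fraction$alpha
  keep <- a > fit$window[1] & a < fit$window[2]
  a <- pmin(pmax(a[keep], 1e-6), 1 - 1e-6)
  d <- tibble(invT = 1 / celsius_to_kelvin(fit$fraction$temperature_C[keep]),
              lnK = log((1 - a) / a))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$invT, y = .data$lnK)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = fit$dH / .Rgas,
                         intercept = -fit$dS_vh / .Rgas,
                         colour = "#b2182b") +
    ggplot2::labs(x = "1 / T (1/K)", y = "ln K",
                  title = sprintf("van't Hoff: ΔH° = %.1f kcal/mol, r² = %.4f",
                                  fit$dH, fit$r2)) +
    ggplot2::theme_minimal()
}

#' Bar chart of candidate fold populations
#'
#' @param scores A `g4_scores` tibble from [score_candidates()].
#' @param top Show at most this many candidates (by population).
#' @return A ggplot object.
#' @export
plot_populations <- function(scores, top = 8L) {
  stopifnot(is.data.frame(scores), "population" %in% names(scores))
  d <- flatten_scores(scores) |>
    mutate(label = sprintf("%s [%s]", .data$descriptor,
                           substr(.data$variant, 1, 40))) |>
    arrange(dplyr::desc(.data$population)) |>
    head(top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, .data$population),
    y = .data$population)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Boltzmann population") +
    ggplot2::theme_minimal()
}
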