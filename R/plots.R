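# ggplot2 displays for the main result types.

#' Plot an x-ray spectrum
#'
#' @param object A spectrum tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xray_spectrum <- function(object, ...) {
  d <- as_tibble(object)
  d$fluence <- d$fluence / (sum(d$fluence) *
                              ifelse(nrow(d) > 1, stats::median(diff(d$energy_keV)), 1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$energy_keV, y = .data$fluence)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "energy (keV)", y = "relative fluence (unit area)",
                  title = sprintf("%g kVp spectrum", attr(object, "kvp"))) +
    ggplot2::theme_minimal()
}

#' Plot a transmission curve
#'
#' Points with (for Monte Carlo curves) 3-sigma error bars, on a log
#' transmission axis.
#'
#' @param object A `transmission_curve`.
#' @param fit Optional `attenuation_fit` drawn as a line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transmission_curve <- function(object, fit = NULL, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$thickness_mm,
                                       y = .data$transmission)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "thickness (mm)", y = "transmission",
                  title = sprintf("%s, %s kVp (%s)", attr(object, "material"),
                                  attr(object, "kvp"), attr(object, "engine"))) +
    ggplot2::theme_minimal()
  if (any(d$stderr > 0)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$transmission * exp(-3 * .data$stderr),
                   ymax = .data$transmission * exp(3 * .data$stderr)),
      width = 0)
  }
  if (!is.null(fit)) {
    tt <- seq(min(d$thickness_mm), max(d$thickness_mm), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(thickness_mm = tt, transmission = predict(fit, tt)),
      linewidth = 0.4)
  }
  p
}

#' Plot the mass-versus-thickness summary
#'
#' Scatter of areal mass against equivalent thickness for every cell,
#' facetted by tube potential, with the non-lead linear trend and the
#' lead-composite reference highlighted.
#'
#' @param object A `shield_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shield_summary <- function(object, ...) {
  d <- mass_thickness_scatter(object)
  tr <- attr(d, "trend")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$thickness_mm, y = .data$mass_kg_m2,
                                  shape = factor(.data$pb_target_mm),
                                  colour = .data$is_lead)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = tr["intercept"], slope = tr["slope"],
                         linetype = "dotted") +
    ggplot2::facet_wrap(~kvp, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 labels = c("lead-free", "Pb-PVC"),
                                 name = NULL) +
    ggplot2::labs(x = "equivalent thickness (mm)", y = "areal mass (kg/m^2)",
                  shape = "Pb target (mm)") +
    ggplot2::theme_minimal()
}
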