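#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot scenario dose summaries
#'
#' Total deposited energy in the chosen breast against photon energy, one
#' line per screen option.
#'
#' @param object An `mc_scenario`.
#' @param which `"left"` (unexposed, default) or `"right"` (exposed) breast.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_scenario
#' @export
autoplot.mc_scenario <- function(object, which = c("left", "right"), ...) {
  which <- match.arg(which)
  s <- object$summary
  ycol <- paste0(which, "_total_eV")
  secol <- paste0(which, "_se_eV")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$energy_keV, y = .data[[ycol]],
                                  colour = .data$screen)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[ycol]] - .data[[secol]],
      ymax = .data[[ycol]] + .data[[secol]])) +
    ggplot2::labs(x = "photon energy (keV)",
                  y = "deposited energy (eV / photon)",
                  colour = "screen",
                  title = paste("Total", which, "breast dose")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mc_scenario
#' @method autoplot mc_tf
#' @export
autoplot.mc_tf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_keV, y = .data$tf,
                                       colour = .data$material)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$tf - .data$se,
                                          ymax = .data$tf + .data$se)) +
    ggplot2::labs(x = "photon energy (keV)", y = "transmission factor",
                  colour = "screen material") +
    ggplot2::theme_minimal()
}

#' Per-layer dose profile of the unexposed breast
#'
#' Deposited energy in the three layers of the left (unexposed) breast by
#' energy and screen option; layer 1 is nearest the source.
#'
#' @param scenario An `mc_scenario`.
#' @return A ggplot object.
#' @export
plot_layer_doses <- function(scenario) {
  ids <- phantom_cell_ids()
  d <- dplyr::filter(scenario$doses, .data$region_id %in% ids$left_layers)
  d$layer <- factor(d$region_id - min(ids$left_layers) + 1L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$energy_keV, y = .data$mean_eV,
                                  colour = .data$layer,
                                  linetype = .data$screen)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "photon energy (keV)",
                  y = "deposited energy (eV / photon)",
                  colour = "left-breast layer", linetype = "screen") +
    ggplot2::theme_minimal()
}
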