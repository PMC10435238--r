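# ggplot2 visualisations for simulation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation result
#'
#' Faceted time-series view of a `synapse_sim`: spine voltage, spine calcium,
#' active CaN/CaMKII, and the plasticity-chain weight, one line per sample.
#'
#' @param object A `synapse_sim` object.
#' @param variables Trajectory columns to facet; defaults to the standard
#'   overview panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synapse_sim <- function(object,
                                 variables = c("v_sp", "ca", "can", "camkii"),
                                 ...) {
  tr <- object$trajectory |>
    dplyr::select("sample", "time", dplyr::all_of(variables)) |>
    tidyr::pivot_longer(-c("sample", "time"),
                        names_to = "variable", values_to = "value") |>
    dplyr::mutate(variable = factor(.data$variable, levels = variables))
  ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$value,
                                   group = .data$sample)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = object$protocol$name) +
    ggplot2::theme_minimal()
}

#' Plot the joint CaN-CaMKII orbit with the plasticity regions
#'
#' @param sim A `synapse_sim` object (or a data frame with `can`, `camkii`).
#' @param params A [synapse_params()] for the region polygons.
#' @return A ggplot object.
#' @export
plot_orbit <- function(sim, params = synapse_params()) {
  df <- if (inherits(sim, "synapse_sim")) sim$trajectory else tibble::as_tibble(sim)
  poly <- dplyr::bind_rows(
    tibble::as_tibble(params$ltp_polygon) |> dplyr::mutate(region = "LTP"),
    tibble::as_tibble(params$ltd_polygon) |> dplyr::mutate(region = "LTD"))
  ggplot2::ggplot(df, ggplot2::aes(.data$can, .data$camkii)) +
    ggplot2::geom_polygon(data = poly,
                          ggplot2::aes(fill = .data$region, group = .data$region),
                          alpha = 0.2, colour = "grey40", inherit.aes = FALSE) +
    ggplot2::geom_path(ggplot2::aes(group = if ("sample" %in% names(df))
      .data$sample else 1), alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "active CaN (uM)", y = "active CaMKII (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time map
#'
#' @param map Output of [dwell_map()].
#' @param params A [synapse_params()] for the region overlays.
#' @return A ggplot object.
#' @export
plot_dwell_map <- function(map, params = synapse_params()) {
  poly <- dplyr::bind_rows(
    tibble::as_tibble(params$ltp_polygon) |> dplyr::mutate(region = "LTP"),
    tibble::as_tibble(params$ltd_polygon) |> dplyr::mutate(region = "LTD"))
  ggplot2::ggplot(map, ggplot2::aes(.data$can, .data$camkii)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$time_s)) +
    ggplot2::geom_polygon(data = poly,
                          ggplot2::aes(group = .data$region), fill = NA,
                          colour = "white", linetype = 2, inherit.aes = FALSE) +
    ggplot2::scale_fill_viridis_c(name = "mean time (s)") +
    ggplot2::labs(x = "active CaN (uM)", y = "active CaMKII (uM)") +
    ggplot2::theme_minimal()
}

#' Plot per-sample weight-change outcomes
#'
#' @param sim A `synapse_sim` object.
#' @return A ggplot object (jittered per-sample outcomes with median bar).
#' @export
plot_outcomes <- function(sim) {
  w <- tidy(sim)
  ggplot2::ggplot(w, ggplot2::aes(x = "", y = .data$weight)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "weight change (%)",
                  title = sim$protocol$name) +
    ggplot2::theme_minimal()
}
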