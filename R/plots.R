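#' Plot insect-mediated fluxes against mean annual temperature
#'
#' Scatter of per-plot gross (H_c) and net (H_i) fluxes on a log scale
#' against MAT, faceted by element, colored by latitude zone.
#'
#' @param fluxes A `flux_table` from [compute_fluxes()].
#' @param plots The plot table of the bundle (for MAT).
#' @param which `"h_c"` or `"h_i"`.
#' @return A ggplot object.
#' @export
plot_flux_mat <- function(fluxes, plots, which = c("h_c", "h_i")) {
  which <- match.arg(which)
  df <- fluxes |>
    filter(is.na(.data$error), !is.na(.data[[which]]),
           .data[[which]] > 0) |>
    left_join(plots |> select("plot_id", "mat"), by = "plot_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mat, y = .data[[which]],
                                   colour = .data$zone)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(
      x = "Mean annual temperature (°C)",
      y = sprintf("%s (g m⁻² y⁻¹, log scale)",
                  toupper(which)),
      colour = "Zone"
    ) +
    ggplot2::theme_minimal()
}

#' Zone summary bar chart
#'
#' Zone means with standard-error bars for one summarised variable.
#'
#' @param summaries Output of [zone_summaries()].
#' @param variable Variable name to display.
#' @return A ggplot object.
#' @export
plot_zone_summary <- function(summaries, variable) {
  df <- summaries |>
    filter(.data$variable == !!variable, .data$zone != "global") |>
    mutate(zone = factor(.data$zone, levels = zone_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone, y = .data$mean)) +
    ggplot2::geom_col(fill = "forestgreen", alpha = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = variable) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flux_table <- function(object, ...) {
  df <- object |>
    filter(is.na(.data$error), !is.na(.data$h_c), .data$h_c > 0) |>
    mutate(zone = factor(.data$zone, levels = zone_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone, y = .data$h_c)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5,
                         ggplot2::aes(colour = .data$zone)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(
      x = NULL,
      y = "Gross insect-mediated flux H_c (g m⁻² y⁻¹)"
    ) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.driver_results <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$predictor,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::facet_wrap(~response) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "Standardized coefficient (95% bootstrap CI)",
                  y = NULL, colour = "CI excludes 0") +
    ggplot2::theme_minimal()
}
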