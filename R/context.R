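#' Zone-level summaries of plot values
#'
#' Mean, standard error and plot count per latitude zone for each requested
#' variable, plus a `global` row over all plots. SE is the sample standard
#' deviation over plots divided by the square root of the number of plots;
#' it is `NA` for a single plot. Empty zones are omitted with a warning.
#'
#' @param data A data frame with one row per plot (or per plot x element)
#'   containing a `zone` column.
#' @param ... Columns to summarise (tidyselect).
#' @param zone Zone column (default `zone`).
#' @return A tibble with `zone`, `variable`, `mean`, `se`, `n`.
#' @examples
#' zone_summaries(
#'   tibble::tibble(zone = c("tropical", "tropical", "boreal"), h = c(1, 2, 3)),
#'   h
#' )
#' @export
zone_summaries <- function(data, ..., zone = "zone") {
  long <- as_tibble(data) |>
    select(zone = dplyr::all_of(zone), ...) |>
    tidyr::pivot_longer(-"zone", names_to = "variable", values_to = "value") |>
    filter(!is.na(.data$value))
  empty <- setdiff(zone_levels, unique(long$zone))
  if (length(empty) > 0 && length(intersect(unique(long$zone), zone_levels)) > 0) {
    warn(paste0("No plots in zone(s): ", paste(empty, collapse = ", ")))
  }
  per_zone <- long |>
    group_by(.data$zone, .data$variable) |>
    summarise(
      mean = mean(.data$value), se = se_mean(.data$value), n = dplyr::n(),
      .groups = "drop"
    )
  global <- long |>
    group_by(.data$variable) |>
    summarise(
      zone = "global", mean = mean(.data$value), se = se_mean(.data$value),
      n = dplyr::n(), .groups = "drop"
    )
  bind_rows(per_zone, global) |>
    arrange(match(.data$zone, c(zone_levels, "global")), .data$variable) |>
    select("zone", "variable", "mean", "se", "n")
}

#' Plot-count-weighted global mean of zone means
#'
#' Combines zone-level means into a global mean weighted by the number of
#' plots per zone. Applied to per-zone means of the same plot values this
#' reproduces the direct all-plot mean exactly.
#'
#' @param means Numeric vector of zone means.
#' @param ns Integer vector of plot counts, same length.
#' @return The weighted mean.
#' @examples
#' weighted_global_mean(c(0.26, 0.11, 0.05), c(33, 32, 9))
#' @export
weighted_global_mean <- function(means, ns) {
  if (length(means) != length(ns)) {
    abort("`means` and `ns` must have the same length.")
  }
  if (any(ns <= 0)) abort("Plot counts must be positive.")
  sum(means * ns) / sum(ns)
}

#' Flux as a percentage of a reference flux
#'
#' Expresses an insect-mediated flux relative to a labile-nutrient reference
#' (atmospheric deposition or bedrock-weathered P) as 100 x flux/reference.
#' Undefined (`NA`) for a zero reference.
#'
#' @param flux Flux value(s), g m-2 y-1.
#' @param reference Reference flux value(s), same units.
#' @return Percent. Vectorized.
#' @examples
#' reference_comparison(0.26, 0.38)
#' @export
reference_comparison <- function(flux, reference) {
  ifelse(!is.na(reference) & reference > 0, 100 * flux / reference, NA_real_)
}

#' Fraction of plots exceeding a reference flux
#'
#' Percentage of plots whose flux is strictly greater than the regional
#' reference mean; ties count as not exceeding.
#'
#' @param values Per-plot flux values.
#' @param reference Scalar regional reference.
#' @return Percent of plots.
#' @examples
#' exceedance_fraction(c(1, 2, 3), 2.5)
#' @export
exceedance_fraction <- function(values, reference) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("No plot values supplied.")
  100 * sum(values > reference) / length(values)
}

#' Compare net insect-mediated N and P fluxes with labile references
#'
#' For each zone, expresses the zone-mean net fluxes H_iN and H_iP as
#' percentages of the zone reference fluxes (atmospheric N, atmospheric P,
#' bedrock-weathered P) and reports the fraction of plots whose flux exceeds
#' the regional reference mean. Zone-level percentages are ratios of zone
#' means by default; set `per_plot = TRUE` to average per-plot ratios
#' instead.
#'
#' @param fluxes A `flux_table` from [compute_fluxes()].
#' @param references Reference table with columns `scope` (zone labels),
#'   `atm_n`, `atm_p`, `bedrock_p`.
#' @param per_plot Average per-plot flux/reference ratios instead of taking
#'   the ratio of zone means.
#' @return A tibble with `zone`, `flux` (variable name), `reference`
#'   (reference name), `flux_mean`, `reference_value`, `percent`,
#'   `exceedance_pct`, `n`.
#' @export
compare_references <- function(fluxes, references, per_plot = FALSE) {
  refs <- references |>
    filter(.data$scope %in% zone_levels) |>
    tidyr::pivot_longer(c("atm_n", "atm_p", "bedrock_p"),
                        names_to = "reference", values_to = "reference_value") |>
    rename(zone = "scope")

  pairs <- tibble(
    flux_name = c("h_i_N", "h_i_P", "h_i_P"),
    el = c("N", "P", "P"),
    ref_name = c("atm_n", "atm_p", "bedrock_p")
  )

  plot_level <- fluxes |>
    filter(.data$element %in% c("N", "P"), is.na(.data$error)) |>
    select("plot_id", "zone", "element", "h_i")

  purrr::pmap_dfr(pairs, function(flux_name, el, ref_name) {
    rf <- refs |> filter(.data$reference == ref_name)
    plot_level |>
      filter(.data$element == el) |>
      inner_join(rf |> select("zone", "reference_value"), by = "zone") |>
      group_by(.data$zone) |>
      summarise(
        flux = flux_name,
        reference = ref_name,
        flux_mean = mean(.data$h_i),
        reference_value = .data$reference_value[1],
        percent = if (per_plot) {
          mean(reference_comparison(.data$h_i, .data$reference_value[1]))
        } else {
          reference_comparison(mean(.data$h_i), .data$reference_value[1])
        },
        exceedance_pct = exceedance_fraction(.data$h_i,
                                             .data$reference_value[1]),
        n = dplyr::n(),
        .groups = "drop"
      )
  }) |>
    arrange(match(.data$zone, zone_levels), .data$flux, .data$reference)
}
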