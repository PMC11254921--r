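#' Annual leaf litterfall for one trap-year
#'
#' Sums the leaf dry mass collected by one litter trap over an annual series
#' of collection intervals and divides by the trap area, giving L_H in
#' g m-2 y-1. There is no extrapolation: litterfall is strongly seasonal, so
#' a series that does not span the year (default threshold 300 days) is an
#' error unless the caller flags it as a complete growing season (e.g. a
#' deciduous stand whose leaf fall is confined to part of the year).
#'
#' @param collections Data frame of collections for one trap: columns
#'   `date_start`, `date_end`, `leaf_dry_mass` (g), `trap_area` (m2).
#' @param complete_season Set `TRUE` to accept a series that covers the full
#'   leaf-fall season but spans fewer than `min_days`.
#' @param min_days Minimum span (first start to last end) accepted without
#'   the `complete_season` flag.
#' @return Annual litterfall, g m-2 y-1.
#' @examples
#' one_year <- tibble::tibble(
#'   date_start = as.Date("2019-01-01") + seq(0, 330, by = 30),
#'   date_end = as.Date("2019-01-01") + seq(30, 360, by = 30),
#'   leaf_dry_mass = rep(10, 12), trap_area = 0.5
#' )
#' trap_annual_litterfall(one_year)
#' @export
trap_annual_litterfall <- function(collections, complete_season = FALSE,
                                   min_days = 300) {
  if (nrow(collections) == 0) abort("No collections supplied.")
  if (length(unique(collections$trap_area)) > 1) {
    abort("Collections for one trap must share a trap area.")
  }
  ord <- order(collections$date_start)
  starts <- as.Date(collections$date_start)[ord]
  ends <- as.Date(collections$date_end)[ord]
  if (any(ends <= starts)) abort("Each interval must end after it starts.")
  if (nrow(collections) > 1 &&
      any(starts[-1] < ends[-length(ends)])) {
    abort("Collection intervals overlap.")
  }
  span <- as.numeric(max(ends) - min(starts))
  if (span < min_days && !complete_season) {
    abort(sprintf(
      paste0("Series spans only %d days (< %d); pass `complete_season = TRUE` ",
             "if it covers the full leaf-fall season."), span, min_days
    ))
  }
  sum(collections$leaf_dry_mass) / collections$trap_area[1]
}

#' Plot-level annual leaf litterfall
#'
#' Computes each trap's annual litterfall, averages traps within a year, and
#' then takes the unweighted mean across the one or two collection years.
#' The standard error is across traps (per year, combined across years as
#' the SE of the mean of year means); it is `NA` for a single trap.
#'
#' @param traps Trap-collection table (columns as in [forest_bundle()]),
#'   possibly covering several plots.
#' @inheritParams trap_annual_litterfall
#' @return A tibble with one row per plot: `plot_id`, `l_h`, `l_h_se`,
#'   `n_traps`, `n_years`.
#' @export
plot_litterfall <- function(traps, complete_season = FALSE, min_days = 300) {
  trap_years <- traps |>
    mutate(.year = format(as.Date(.data$date_start), "%Y")) |>
    group_by(.data$plot_id, .data$.year, .data$trap_id) |>
    group_modify(~ tibble(annual = trap_annual_litterfall(
      .x, complete_season = complete_season, min_days = min_days
    ))) |>
    ungroup()

  year_level <- trap_years |>
    group_by(.data$plot_id, .data$.year) |>
    summarise(
      l_h = mean(.data$annual),
      se = se_mean(.data$annual),
      n_traps = dplyr::n(),
      .groups = "drop"
    )

  year_level |>
    group_by(.data$plot_id) |>
    summarise(
      l_h = mean(.data$l_h),
      l_h_se = if (all(is.na(.data$se))) NA_real_ else
        sqrt(sum(.data$se^2)) / dplyr::n(),
      n_traps = max(.data$n_traps),
      n_years = dplyr::n(),
      .groups = "drop"
    )
}

#' Foliar biomass production from litterfall and herbivory
#'
#' Litter traps only catch the leaf mass that survived folivory, so annual
#' foliar biomass production is reconstructed as FP = L_H / (1 - H). FP is
#' never below L_H, with equality exactly when no leaf area was removed.
#'
#' @param l_h Annual leaf litterfall, g m-2 y-1.
#' @param h Herbivory rate (fraction of leaf area removed), in `[0, 1)`.
#' @return FP, g m-2 y-1. Vectorized.
#' @examples
#' foliar_production(200, 0.05)
#' @export
foliar_production <- function(l_h, h) {
  if (any(h < 0 | h >= 1, na.rm = TRUE)) {
    abort("Herbivory rate must be in [0, 1).")
  }
  if (any(h > 0.5, na.rm = TRUE)) {
    warn("Herbivory rate above 0.5 is outside the range observed in mature broadleaved forests.")
  }
  l_h / (1 - h)
}

#' Gross insect-mediated element flux
#'
#' The total mass of element E in foliage consumed by folivores per ground
#' area and year: H_c = FP x F_E x H. Under the steady-state assumption the
#' same mass returns to the forest floor as frass, bodies, moults and
#' unconsumed fragments.
#'
#' @param fp Foliar biomass production, g m-2 y-1.
#' @param f_e Green-leaf concentration of the element (mass fraction).
#' @param h Herbivory rate (fraction).
#' @return H_c, g m-2 y-1. Vectorized.
#' @examples
#' gross_flux(fp = 500, f_e = 0.02, h = 0.05)
#' @export
gross_flux <- function(fp, f_e, h) {
  fp * f_e * h
}

#' Senescence mass-loss correction factor
#'
#' Leaves lose dry mass between the green and freshly senesced state, so
#' litter concentrations must be corrected before comparing them with green
#' leaves. The factors are 0.78 for predominantly evergreen and 0.784 for
#' predominantly deciduous angiosperm forests.
#'
#' @param phenology `"evergreen"` or `"deciduous"` (vectorized).
#' @return MLCF, the ratio of senesced to green leaf dry mass.
#' @export
mass_loss_correction <- function(phenology) {
  bad <- setdiff(unique(phenology), phenology_levels)
  if (length(bad) > 0) {
    abort(paste0("Unknown phenology label(s): ", paste(bad, collapse = ", ")))
  }
  ifelse(phenology == "evergreen", 0.78, 0.784)
}

#' Nutrient resorption efficiency
#'
#' The proportion of an element withdrawn from the leaf before abscission,
#' computed from green-leaf and senesced-litter concentrations with the
#' senescence mass-loss correction: RE = 1 - (c_litter / f_green) x MLCF.
#' Defined for C, N and P; silicon is not resorbed and requesting it is an
#' error. Values outside `[0, 1]` (possible with noisy chemistry) are
#' returned unclamped and flagged with a warning so downstream net fluxes
#' are not silently biased.
#'
#' @param f_green Green-leaf mass fraction of the element.
#' @param c_litter Senesced-litter mass fraction of the element.
#' @param mlcf Mass-loss correction factor (see [mass_loss_correction()]).
#' @param element Element label, used only to reject Si.
#' @return RE as a fraction. Vectorized.
#' @examples
#' resorption_efficiency(f_green = 0.02, c_litter = 0.01, mlcf = 0.784)
#' @export
resorption_efficiency <- function(f_green, c_litter, mlcf, element = "N") {
  if (any(element == "Si")) {
    abort("Resorption efficiency is not defined for Si.")
  }
  if (any(f_green <= 0, na.rm = TRUE) || any(c_litter <= 0, na.rm = TRUE)) {
    abort("Concentrations must be positive.")
  }
  re <- 1 - (c_litter / f_green) * mlcf
  out_of_range <- !is.na(re) & (re < 0 | re > 1)
  if (any(out_of_range)) {
    warn(sprintf("%d resorption value(s) outside [0, 1]; returned unclamped.",
                 sum(out_of_range)))
  }
  re
}

#' Net insect-mediated element flux
#'
#' The additional element input to soil caused by folivores intercepting
#' green foliage before resorption: H_i = H_c x RE. This equals the
#' three-term difference L_EH + H_c - L_E between the with-herbivore and
#' no-herbivore litter element budgets (see
#' [counterfactual_litter_flux()]). Defined for C, N and P only.
#'
#' @param h_c Gross insect-mediated flux, g m-2 y-1.
#' @param re Resorption efficiency (fraction).
#' @param element Element label, used only to reject Si.
#' @return H_i, g m-2 y-1. Vectorized.
#' @examples
#' net_flux(h_c = 0.082, re = 0.618)
#' @export
net_flux <- function(h_c, re, element = "N") {
  if (any(element == "Si")) {
    abort("Net insect-mediated flux is not defined for Si.")
  }
  h_c * re
}

#' Observed litter element flux
#'
#' Annual element return in collected leaf litter: L_EH = L_H x c_litter.
#'
#' @param l_h Annual leaf litterfall, g m-2 y-1.
#' @param c_litter Litter mass fraction of the element.
#' @return L_EH, g m-2 y-1. Vectorized.
#' @export
litter_element_flux <- function(l_h, c_litter) {
  l_h * c_litter
}

#' Counterfactual no-herbivore litter element flux
#'
#' The litter element flux that would have been observed had the consumed
#' foliage not been eaten: the consumed mass FP x H, senescing normally,
#' would shrink by the mass-loss factor and fall at the litter
#' concentration, so L_E = L_EH + FP x H x MLCF x c_litter. By
#' construction, L_EH + H_c - L_E = H_c x RE to machine precision.
#'
#' @param l_eh Observed litter element flux, g m-2 y-1.
#' @param fp Foliar biomass production, g m-2 y-1.
#' @param h Herbivory rate (fraction).
#' @param c_litter Litter mass fraction of the element.
#' @param mlcf Mass-loss correction factor.
#' @return L_E, g m-2 y-1. Vectorized.
#' @export
counterfactual_litter_flux <- function(l_eh, fp, h, c_litter, mlcf) {
  l_eh + fp * h * mlcf * c_litter
}

#' Ratio of consumed to litter element flux
#'
#' H_c relative to the observed litter flux of the same element; `NA` when
#' the litter flux is zero.
#'
#' @param h_c Gross insect-mediated flux, g m-2 y-1.
#' @param l_eh Observed litter element flux, g m-2 y-1.
#' @return Dimensionless ratio. Vectorized.
#' @export
hc_to_litter_ratio <- function(h_c, l_eh) {
  ifelse(l_eh > 0, h_c / l_eh, NA_real_)
}

#' Per-plot, per-element flux table
#'
#' Orchestrates the full mass-balance accounting over a dataset bundle:
#' plot-level herbivory from the damage tallies, annual litterfall from the
#' trap collections, foliar production, then the element fluxes H_c, L_EH,
#' L_E and (for C, N, P) RE and H_i. Silicon rows carry the gross flux only;
#' their `re`, `h_i` and `l_e` are `NA`. Plots missing chemistry for a
#' requested element are recorded in the `error` column and do not stop the
#' pipeline.
#'
#' @param bundle A [forest_bundle()].
#' @param elements Elements to account for (subset of C, N, P, Si).
#' @param scheme A [damage_class_scheme()].
#' @inheritParams trap_annual_litterfall
#' @return A tibble of class `flux_table`, one row per plot x element, with
#'   columns `plot_id`, `site_id`, `zone`, `element`, `l_h`, `l_h_se`, `h`,
#'   `incidence`, `fp`, `f_green`, `c_litter`, `mlcf`, `h_c`, `re`,
#'   `re_flag`, `h_i`, `l_eh`, `l_e`, `hc_litter_ratio`, `error`.
#' @export
compute_fluxes <- function(bundle, elements = c("C", "N", "P", "Si"),
                           scheme = damage_class_scheme(),
                           complete_season = FALSE, min_days = 300) {
  stopifnot(inherits(bundle, "forest_bundle"))
  elements <- match.arg(elements, element_levels, several.ok = TRUE)

  herb <- estimate_herbivory(bundle$damage, scheme)
  lf <- plot_litterfall(bundle$traps, complete_season = complete_season,
                        min_days = min_days)

  base <- bundle$plots |>
    select("plot_id", "site_id", "zone", "phenology") |>
    mutate(mlcf = mass_loss_correction(.data$phenology)) |>
    left_join(herb, by = "plot_id") |>
    left_join(lf, by = "plot_id")

  grid <- tidyr::crossing(base, element = elements)
  chem <- bundle$chemistry |>
    select("plot_id", "element", "f_green", "c_litter")
  out <- grid |>
    left_join(chem, by = c("plot_id", "element")) |>
    mutate(
      error = dplyr::case_when(
        is.na(.data$h) ~ "no damage tallies",
        is.na(.data$l_h) ~ "no trap collections",
        is.na(.data$f_green) | is.na(.data$c_litter) ~ "missing chemistry",
        TRUE ~ NA_character_
      ),
      fp = ifelse(is.na(.data$error) | .data$error == "missing chemistry",
                  foliar_production(.data$l_h, .data$h), NA_real_),
      h_c = gross_flux(.data$fp, .data$f_green, .data$h),
      re = ifelse(
        .data$element == "Si" | is.na(.data$f_green), NA_real_,
        1 - (.data$c_litter / .data$f_green) * .data$mlcf
      ),
      re_flag = !is.na(.data$re) & (.data$re < 0 | .data$re > 1),
      h_i = ifelse(.data$element == "Si", NA_real_, .data$h_c * .data$re),
      l_eh = litter_element_flux(.data$l_h, .data$c_litter),
      l_e = ifelse(
        .data$element == "Si", NA_real_,
        counterfactual_litter_flux(.data$l_eh, .data$fp, .data$h,
                                   .data$c_litter, .data$mlcf)
      ),
      hc_litter_ratio = hc_to_litter_ratio(.data$h_c, .data$l_eh)
    ) |>
    select(
      "plot_id", "site_id", "zone", "element", "l_h", "l_h_se", "h",
      "incidence", "fp", "f_green", "c_litter", "mlcf", "h_c", "re",
      "re_flag", "h_i", "l_eh", "l_e", "hc_litter_ratio", "error"
    ) |>
    arrange(.data$plot_id, match(.data$element, element_levels))
  if (any(out$re_flag, na.rm = TRUE)) {
    warn(sprintf("%d resorption value(s) outside [0, 1] (see `re_flag`).",
                 sum(out$re_flag, na.rm = TRUE)))
  }
  class(out) <- c("flux_table", class(out))
  out
}

#' Write a flux table to CSV
#'
#' Percent-style quantities (`h`, `incidence`, `re`) are written as percent;
#' a leading comment line documents the units.
#'
#' @param fluxes A `flux_table` from [compute_fluxes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(fluxes, path) {
  out <- fluxes |>
    mutate(
      h_pct = fraction_to_pct(.data$h),
      incidence_pct = fraction_to_pct(.data$incidence),
      re_pct = fraction_to_pct(.data$re),
      f_green_pct = fraction_to_pct(.data$f_green),
      c_litter_pct = fraction_to_pct(.data$c_litter)
    ) |>
    select(
      "plot_id", "site_id", "zone", "element", "l_h", "h_pct",
      "incidence_pct", "fp", "f_green_pct", "c_litter_pct", "mlcf", "h_c",
      "re_pct", "h_i", "l_eh", "l_e", "hc_litter_ratio", "error"
    )
  con <- file(path, "w")
  writeLines(paste0(
    "# fluxes: l_h/fp/h_c/h_i/l_eh/l_e in g m-2 y-1; ",
    "h/incidence/re/concentrations in percent; mlcf dimensionless"
  ), con)
  close(con)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
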