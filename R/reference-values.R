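#' Published-style zone reference values for a global broadleaved network
#'
#' Zone-level summary statistics (mean, standard error, number of plots)
#' typical of a global network of 74 mature broadleaved-forest plots
#' (33 tropical, 32 temperate, 9 boreal), bundled as a worked-example
#' input: foliar biomass production, herbivory rate, gross and net
#' insect-mediated element fluxes, resorption efficiencies, and the labile
#' reference fluxes (atmospheric N and P deposition, bedrock-weathered P).
#' `fp` is the plot-level zone mean; `fp_narrative` is the site-level zone
#' mean usually quoted when contrasting zones.
#'
#' Units: `fp*` in g m-2 y-1; `h_pct` and `re_*_pct` in percent;
#' `h_c_*`, `h_i_*` and the reference fluxes in g m-2 y-1.
#'
#' @return A tibble with columns `variable`, `zone`, `mean`, `se`, `n`.
#' @examples
#' zr <- zone_reference_values()
#' subset(zr, variable == "h_i_N")
#' @export
zone_reference_values <- function() {
  z <- c("tropical", "temperate", "boreal")
  n <- c(33L, 32L, 9L)
  row <- function(variable, mean, se) {
    tibble(variable = variable, zone = z, mean = mean, se = se, n = n)
  }
  bind_rows(
    row("fp", c(513.0, 321.6, 231.9), c(10.2, 7.3, 17.5)),
    row("fp_narrative", c(539.3, 323.4, 158.8), c(42.6, 28.6, 47.6)),
    row("h_pct", c(5.4, 3.3, 2.4), c(0.2, 0.1, 0.2)),
    row("h_c_C", c(15.87, 5.41, 1.65), c(0.90, 0.90, 0.58)),
    row("h_c_N", c(0.600, 0.231, 0.082), c(0.038, 0.038, 0.029)),
    row("h_c_P", c(0.034, 0.016, 0.006), c(0.003, 0.003, 0.002)),
    row("h_c_Si", c(0.178, 0.178, 0.029), c(0.076, 0.76, 0.012)),
    row("h_i_N", c(0.26, 0.11, 0.05), c(0.04, 0.02, 0.02)),
    row("h_i_P", c(0.022, 0.009, 0.003), c(0.004, 0.002, 0.001)),
    row("re_n_pct", c(46.5, NA, 61.8), c(2.7, NA, 3.3)),
    row("re_p_pct", c(66.5, 57.9, 55.2), c(2.1, 2.1, 4.5)),
    row("atm_n", c(0.38, 1.03, 0.49), c(0.08, 0.14, 0.12)),
    row("atm_p", c(0.005, 0.004, 0.003), c(0.001, 0.001, 0.001)),
    row("bedrock_p", c(0.054, 0.045, 0.069), c(0.019, 0.015, 0.037))
  )
}
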