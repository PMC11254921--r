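#' Configuration for the synthetic plot-network generator
#'
#' Defaults emulate the design of a global broadleaved-forest herbivory
#' network: sites spanning mean annual temperatures of -2 to 27 C and
#' dryness (PET/MAP) 0.21 to 1.30, 9--25 litter traps of 0.1--0.5 m2 per
#' plot collected roughly monthly, quarterly leaf-damage scans, zone
#' assignment by MAT terciles (boreal coldest, tropical warmest), herbivory
#' driven by MAT on the logit scale with a site-level random effect, foliar
#' production driven by MAT and soil C:N on the log scale, zone-dependent
#' green-leaf chemistry and resorption, and damage incidence of about twelve
#' times the herbivory rate. Litter chemistry is constructed exactly as
#' `c_litter = f_green * (1 - RE) / MLCF`, so the resorption calculation
#' recovers the generator's true RE identically.
#'
#' @param n_sites Number of sites.
#' @param plots_per_site Integer range `c(min, max)` of plots per site.
#' @param traps_per_plot Integer range of litter traps per plot.
#' @param trap_area Range of trap areas, m2.
#' @param leaves_per_scan Leaves scored per damage scan.
#' @param scans_per_year Damage scans per year.
#' @param years Collection years per plot (1 or 2).
#' @param mat_range MAT range across sites, degrees C.
#' @param dryness_range PET/MAP range across sites.
#' @param h_logit_intercept,h_mat_slope Herbivory model on the logit scale:
#'   `logit(H) = intercept + slope * z(MAT) + site effect + plot effect`.
#' @param h_site_sd,h_plot_sd Standard deviations of the site and plot
#'   effects on the logit scale.
#' @param fp_log_intercept,fp_mat_slope,fp_soilcn_slope,fp_site_sd,fp_plot_sd
#'   Foliar-production model on the log scale:
#'   `log(FP) = intercept + mat_slope * z(MAT) + soilcn_slope * z(soil C:N)
#'   + site effect + plot effect` (g m-2 y-1).
#' @param incidence_ratio Damage incidence as a multiple of H (capped at
#'   `incidence_max`).
#' @param incidence_max Upper cap on incidence.
#' @param damage_shape Concentration of the beta distribution of per-leaf
#'   damage among damaged leaves (small values give the strongly
#'   right-skewed damage typical of background herbivory).
#' @param re_means Named list per element (`C`, `N`, `P`) of zone-ordered
#'   (tropical, temperate, boreal) true resorption efficiencies.
#' @param re_sd Plot-level SD of true resorption.
#' @param chem_means Named list per element of zone-ordered green-leaf
#'   concentrations (% dry mass).
#' @param chem_cv Plot-level coefficient of variation of green chemistry.
#' @param trap_sd SD of the mean-one lognormal trap-mass noise.
#' @param seed Default seed for [generate_network()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_sites = 40,
    plots_per_site = c(1, 3),
    traps_per_plot = c(9, 25),
    trap_area = c(0.1, 0.5),
    leaves_per_scan = 400,
    scans_per_year = 4,
    years = 1,
    mat_range = c(-2, 27),
    dryness_range = c(0.21, 1.30),
    h_logit_intercept = stats::qlogis(0.04),
    h_mat_slope = 0.4,
    h_site_sd = 0.3,
    h_plot_sd = 0.1,
    fp_log_intercept = log(350),
    fp_mat_slope = 0.35,
    fp_soilcn_slope = -0.15,
    fp_site_sd = 0.15,
    fp_plot_sd = 0.15,
    incidence_ratio = 12,
    incidence_max = 0.95,
    damage_shape = 1.2,
    re_means = list(
      C = c(tropical = 0.20, temperate = 0.20, boreal = 0.20),
      N = c(tropical = 0.465, temperate = 0.53, boreal = 0.618),
      P = c(tropical = 0.665, temperate = 0.579, boreal = 0.552)
    ),
    re_sd = 0.04,
    chem_means = list(
      C = c(tropical = 48, temperate = 48, boreal = 48),
      N = c(tropical = 1.9, temperate = 2.3, boreal = 2.4),
      P = c(tropical = 0.09, temperate = 0.14, boreal = 0.13),
      Si = c(tropical = 0.5, temperate = 0.4, boreal = 0.3)
    ),
    chem_cv = 0.10,
    trap_sd = 0.3,
    seed = 20240717) {
  cfg <- as.list(environment())
  stopifnot(
    n_sites >= 3, years %in% c(1, 2),
    plots_per_site[1] >= 1, plots_per_site[2] >= plots_per_site[1],
    traps_per_plot[1] >= 1, trap_area[1] > 0, trap_area[2] <= 1,
    leaves_per_scan > 0, scans_per_year >= 1,
    diff(mat_range) > 0, diff(dryness_range) > 0,
    incidence_ratio > 1, incidence_max > 0 && incidence_max < 1,
    damage_shape > 0, re_sd >= 0, chem_cv >= 0, trap_sd >= 0
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# beta mean whose class-binned midpoint expectation equals `target`:
# makes the midpoint estimator of H exactly unbiased under the generator
match_beta_mean <- function(target, shape, scheme) {
  mids <- scheme$midpoints
  bounds <- scheme$bounds
  if (target <= min(mids) || target >= max(mids)) {
    abort(sprintf("Conditional damage mean %.4g outside attainable (%g, %g).",
                  target, min(mids), max(mids)))
  }
  binned_mean <- function(mu) {
    p <- diff(stats::pbeta(bounds, mu * shape, (1 - mu) * shape))
    sum(p * mids)
  }
  stats::uniroot(function(mu) binned_mean(mu) - target,
                 lower = 1e-6, upper = 1 - 1e-6, tol = 1e-12)$root
}

# per-leaf class probabilities (undamaged + 6 classes) for one plot
damage_class_probs <- function(h_true, incidence, shape, scheme) {
  mu <- match_beta_mean(h_true / incidence, shape, scheme)
  p <- diff(stats::pbeta(scheme$bounds, mu * shape, (1 - mu) * shape))
  c(1 - incidence, incidence * p)
}

#' Generate a synthetic forest plot network with known ground truth
#'
#' Simulates a complete dataset bundle (plots, soil, trap collections,
#' damage tallies, chemistry, references) with the statistical structure the
#' flux and driver analyses assume, and attaches the generating truth so
#' estimates can be checked against it. See [synthetic_config()] for the
#' data-generating model. Reference fluxes are fixed zone-level values
#' typical of atmospheric N and P deposition and bedrock P weathering in
#' tropical, temperate and boreal broadleaved forests.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the entire bundle is a deterministic function
#'   of `config` and `seed`.
#' @param scheme A [damage_class_scheme()].
#' @return A [forest_bundle()] with attribute `truth` (see
#'   [ground_truth()]).
#' @export
generate_network <- function(config = synthetic_config(),
                             seed = config$seed,
                             scheme = damage_class_scheme()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)

  # --- sites -----------------------------------------------------------
  n_sites <- config$n_sites
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  mat <- stats::runif(n_sites, config$mat_range[1], config$mat_range[2])
  dryness <- stats::runif(n_sites, config$dryness_range[1],
                          config$dryness_range[2])
  terciles <- stats::quantile(mat, c(1 / 3, 2 / 3))
  zone <- dplyr::case_when(
    mat <= terciles[1] ~ "boreal",
    mat <= terciles[2] ~ "temperate",
    TRUE ~ "tropical"
  )
  site_h_eff <- stats::rnorm(n_sites, 0, config$h_site_sd)
  site_fp_eff <- stats::rnorm(n_sites, 0, config$fp_site_sd)

  # --- plots -----------------------------------------------------------
  # sample.int-based draw: immune to sample()'s scalar expansion when the
  # range collapses to one value
  draw_range <- function(range, n) {
    pool <- seq(range[1], range[2])
    pool[sample.int(length(pool), n, replace = TRUE)]
  }
  n_plots_site <- draw_range(config$plots_per_site, n_sites)
  sites <- tibble(
    site_id = site_ids, mat = mat, dryness = dryness, zone = zone,
    site_h_eff = site_h_eff, site_fp_eff = site_fp_eff,
    n_plots = n_plots_site
  )
  plots <- sites |>
    tidyr::uncount(.data$n_plots, .id = "plot_no") |>
    mutate(plot_id = sprintf("%s-P%d", .data$site_id, .data$plot_no))
  np <- nrow(plots)

  z_mat <- as.numeric(zscore(plots$mat))
  plots <- plots |>
    mutate(
      abs_lat = dplyr::case_when(
        .data$zone == "tropical" ~ stats::runif(np, 0, 23),
        .data$zone == "temperate" ~ stats::runif(np, 28, 55),
        TRUE ~ stats::runif(np, 55, 68)
      ),
      latitude = .data$abs_lat * sample(c(-1, 1), np, replace = TRUE,
                                        prob = c(0.25, 0.75)),
      phenology = dplyr::case_when(
        .data$zone == "tropical" ~ "evergreen",
        .data$zone == "boreal" ~ "deciduous",
        TRUE ~ sample(c("deciduous", "evergreen"), np, replace = TRUE,
                      prob = c(0.8, 0.2))
      ),
      map = stats::runif(np, 500, 3000),
      pet = .data$dryness * .data$map,
      n_traps = draw_range(config$traps_per_plot, np)
    )

  # --- soil ------------------------------------------------------------
  cn_mean <- c(tropical = 12, temperate = 14, boreal = 18)
  cp_mean <- c(tropical = 300, temperate = 120, boreal = 80)
  sc_mean <- c(tropical = 3, temperate = 6, boreal = 9)
  soil <- plots |>
    mutate(
      s_c = pmin(0.272, unname(sc_mean[.data$zone]) *
                   stats::rlnorm(np, -0.125, 0.5) / 100),
      s_cn = pmax(5, unname(cn_mean[.data$zone]) *
                    stats::rlnorm(np, -0.02, 0.2)),
      s_cp = pmax(20, unname(cp_mean[.data$zone]) *
                    stats::rlnorm(np, -0.045, 0.3)),
      s_n = .data$s_c / .data$s_cn,
      s_p = .data$s_c / .data$s_cp,
      s_si = stats::runif(np, 0.005, 0.15)
    ) |>
    select("plot_id", "s_c", "s_n", "s_p", "s_si", "s_cn", "s_cp")

  # --- latent plot-level truth ----------------------------------------
  z_cn <- as.numeric(zscore(soil$s_cn))
  h_true <- stats::plogis(
    config$h_logit_intercept + config$h_mat_slope * z_mat +
      plots$site_h_eff + stats::rnorm(np, 0, config$h_plot_sd)
  )
  if (any(h_true <= 0 | h_true >= 0.5)) {
    abort("Configuration produced true herbivory outside (0, 0.5).")
  }
  fp_true <- exp(
    config$fp_log_intercept + config$fp_mat_slope * z_mat +
      config$fp_soilcn_slope * z_cn + plots$site_fp_eff +
      stats::rnorm(np, 0, config$fp_plot_sd)
  )
  l_h_true <- fp_true * (1 - h_true)
  incidence_true <- pmin(config$incidence_ratio * h_true,
                         config$incidence_max)
  mlcf <- mass_loss_correction(plots$phenology)

  # --- chemistry (litter derived exactly from true resorption) ---------
  chem <- purrr::map_dfr(names(config$chem_means), function(el) {
    f_green <- unname(config$chem_means[[el]][plots$zone]) / 100 *
      stats::rlnorm(np, -config$chem_cv^2 / 2, config$chem_cv)
    if (el == "Si") {
      re_true <- rep(NA_real_, np)
      c_litter <- f_green / mlcf  # no resorption of Si
    } else {
      re_true <- pmin(0.9, pmax(
        0.05, unname(config$re_means[[el]][plots$zone]) +
          stats::rnorm(np, 0, config$re_sd)
      ))
      c_litter <- f_green * (1 - re_true) / mlcf
    }
    tibble(
      plot_id = plots$plot_id, element = el, f_green = f_green,
      c_litter = c_litter, re_true = re_true, season = "annual"
    )
  })

  # --- trap collections (mean-one lognormal trap noise, monthly) -------
  month_starts <- as.Date("2019-01-01") +
    round(365 * (0:11) / 12)
  month_ends <- c(month_starts[-1], as.Date("2020-01-01"))
  traps <- purrr::map_dfr(seq_len(np), function(i) {
    nt <- plots$n_traps[i]
    purrr::map_dfr(seq_len(config$years), function(yr) {
      offset <- 365 * (yr - 1)
      area <- stats::runif(nt, config$trap_area[1], config$trap_area[2])
      annual_mass <- l_h_true[i] * area *
        stats::rlnorm(nt, -config$trap_sd^2 / 2, config$trap_sd)
      tidyr::crossing(trap = seq_len(nt), month = 1:12) |>
        mutate(
          trap_id = sprintf("%s-T%02d", plots$plot_id[i], .data$trap),
          plot_id = plots$plot_id[i],
          date_start = month_starts[.data$month] + offset,
          date_end = month_ends[.data$month] + offset,
          leaf_dry_mass = annual_mass[.data$trap] / 12,
          trap_area = area[.data$trap]
        ) |>
        select("trap_id", "plot_id", "date_start", "date_end",
               "leaf_dry_mass", "trap_area")
    })
  })

  # --- damage tallies --------------------------------------------------
  scan_dates <- as.Date("2019-01-01") +
    round(365 * (seq_len(config$scans_per_year) - 0.5) /
            config$scans_per_year)
  damage <- purrr::map_dfr(seq_len(np), function(i) {
    probs <- damage_class_probs(h_true[i], incidence_true[i],
                                config$damage_shape, scheme)
    purrr::map_dfr(seq_len(config$years), function(yr) {
      purrr::map_dfr(seq_len(config$scans_per_year), function(s) {
        counts <- as.integer(
          stats::rmultinom(1, config$leaves_per_scan, probs)
        )
        tibble(
          plot_id = plots$plot_id[i],
          scan_date = scan_dates[s] + 365 * (yr - 1),
          n_undamaged = counts[1],
          n_c1 = counts[2], n_c2 = counts[3], n_c3 = counts[4],
          n_c4 = counts[5], n_c5 = counts[6], n_c6 = counts[7]
        )
      })
    })
  })

  # --- references (typical zone-mean labile inputs, g m-2 y-1) ---------
  references <- tibble(
    scope = c("tropical", "temperate", "boreal"),
    atm_n = c(0.38, 1.03, 0.49),
    atm_p = c(0.005, 0.004, 0.003),
    bedrock_p = c(0.054, 0.045, 0.069)
  )

  plots_tbl <- plots |>
    transmute(
      plot_id = .data$plot_id, site_id = .data$site_id,
      latitude = .data$latitude, zone = .data$zone, mat = .data$mat,
      pet = .data$pet, map = .data$map, phenology = .data$phenology,
      n_traps = .data$n_traps,
      trap_area = mean(config$trap_area)
    )

  bundle <- forest_bundle(
    plots = plots_tbl,
    soil = soil,
    traps = traps,
    damage = damage,
    chemistry = chem |> select("plot_id", "element", "f_green", "c_litter",
                               "season"),
    references = references
  )

  truth <- list(
    config = config,
    seed = seed,
    slopes = c(h_mat_slope = config$h_mat_slope,
               fp_mat_slope = config$fp_mat_slope,
               fp_soilcn_slope = config$fp_soilcn_slope),
    plots = tibble(
      plot_id = plots$plot_id, site_id = plots$site_id, zone = plots$zone,
      mat = plots$mat, dryness = plots$dryness,
      h_true = h_true, incidence_true = incidence_true,
      fp_true = fp_true, l_h_true = l_h_true, mlcf = mlcf
    ),
    chemistry = chem |> select("plot_id", "element", "f_green", "c_litter",
                               "re_true")
  )
  attr(bundle, "truth") <- truth
  bundle
}

#' Ground truth of a synthetic bundle
#'
#' Returns the generating parameter vector and per-plot latent values
#' (true H, incidence, FP, L_H, RE) of a bundle produced by
#' [generate_network()], for parameter-recovery tests.
#'
#' @param bundle A [forest_bundle()] from [generate_network()].
#' @return A list with `config`, `seed`, `slopes`, `plots` (per-plot latent
#'   values) and `chemistry` (per plot x element truth including `re_true`).
#' @export
ground_truth <- function(bundle) {
  truth <- attr(bundle, "truth")
  if (is.null(truth)) {
    abort("Not a synthetic bundle: no ground truth attached.")
  }
  truth
}
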