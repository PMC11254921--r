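# shared fixtures: tiny handmade bundles and damage tallies

tally_row <- function(n_undamaged, counts, plot_id = "p1",
                      scan_date = as.Date("2019-06-01")) {
  tibble::tibble(
    plot_id = plot_id, scan_date = scan_date, n_undamaged = n_undamaged,
    n_c1 = counts[1], n_c2 = counts[2], n_c3 = counts[3],
    n_c4 = counts[4], n_c5 = counts[5], n_c6 = counts[6]
  )
}

monthly_collections <- function(trap_id = "t1", plot_id = "p1", mass = 10,
                                area = 0.5, year = 2019) {
  origin <- as.Date(sprintf("%d-01-01", year))
  starts <- origin + round(365 * (0:11) / 12)
  ends <- c(starts[-1], origin + 365)
  tibble::tibble(
    trap_id = trap_id, plot_id = plot_id,
    date_start = starts, date_end = ends,
    leaf_dry_mass = mass, trap_area = area
  )
}

# a 2-plot handmade bundle with exactly known fluxes
tiny_bundle <- function() {
  plots <- tibble::tibble(
    plot_id = c("p1", "p2"), site_id = c("s1", "s2"),
    latitude = c(-3, 48), zone = c("tropical", "temperate"),
    mat = c(25, 8), pet = c(1200, 600), map = c(2000, 800),
    phenology = c("evergreen", "deciduous"),
    n_traps = c(2L, 1L), trap_area = c(0.5, 0.25)
  )
  soil <- tibble::tibble(
    plot_id = c("p1", "p2"), s_c = c(0.03, 0.06), s_n = c(0.002, 0.004),
    s_p = c(0.0001, 0.0005), s_si = c(0.02, 0.05),
    s_cn = c(15, 15), s_cp = c(300, 120)
  )
  traps <- dplyr::bind_rows(
    monthly_collections("t1", "p1", mass = 10, area = 0.5),
    monthly_collections("t2", "p1", mass = 12, area = 0.5),
    monthly_collections("t3", "p2", mass = 5, area = 0.25)
  )
  damage <- dplyr::bind_rows(
    tally_row(50, c(0, 50, 0, 0, 0, 0), plot_id = "p1"),   # H = 0.015
    tally_row(80, c(0, 0, 20, 0, 0, 0), plot_id = "p2")    # H = 0.03
  )
  chemistry <- tidyr::crossing(
    plot_id = c("p1", "p2"),
    tibble::tibble(
      element = c("C", "N", "P", "Si"),
      f_green = c(0.48, 0.02, 0.001, 0.004),
      c_litter = c(0.49, 0.011, 0.0005, 0.005)
    )
  ) |>
    dplyr::mutate(season = "annual")
  references <- tibble::tibble(
    scope = c("tropical", "temperate", "boreal"),
    atm_n = c(0.38, 1.03, 0.49),
    atm_p = c(0.005, 0.004, 0.003),
    bedrock_p = c(0.054, 0.045, 0.069)
  )
  herbflux::forest_bundle(plots, soil, traps, damage, chemistry, references)
}

expect_tables_equal <- function(a, b, tol = 1e-9) {
  expect_identical(names(a), names(b))
  expect_equal(nrow(a), nrow(b))
  for (col in names(a)) {
    if (is.numeric(a[[col]])) {
      expect_equal(a[[col]], b[[col]], tolerance = tol)
    } else {
      expect_equal(as.character(a[[col]]), as.character(b[[col]]))
    }
  }
}
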