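test_that("trap annual litterfall sums mass over the series per unit area", {
  full_year <- tibble::tibble(
    date_start = as.Date("2019-01-01"), date_end = as.Date("2019-12-31"),
    leaf_dry_mass = 50, trap_area = 0.25
  )
  expect_equal(trap_annual_litterfall(full_year), 200)
  expect_equal(trap_annual_litterfall(monthly_collections(mass = 10, area = 0.5)),
               240)

  short <- tibble::tibble(
    date_start = as.Date("2019-01-01"), date_end = as.Date("2019-04-11"),
    leaf_dry_mass = 30, trap_area = 0.5
  )
  expect_error(trap_annual_litterfall(short), "complete_season")
  expect_equal(trap_annual_litterfall(short, complete_season = TRUE), 60)

  overlapping <- tibble::tibble(
    date_start = as.Date(c("2019-01-01", "2019-06-01")),
    date_end = as.Date(c("2019-07-01", "2019-12-31")),
    leaf_dry_mass = 10, trap_area = 0.5
  )
  expect_error(trap_annual_litterfall(overlapping), "overlap")
})

test_that("plot litterfall averages traps within years, then years", {
  traps <- dplyr::bind_rows(
    monthly_collections("t1", mass = 200 / 24, area = 0.5),
    monthly_collections("t2", mass = 240 / 24, area = 0.5),
    monthly_collections("t3", mass = 280 / 24, area = 0.5)
  )
  res <- plot_litterfall(traps)
  expect_equal(res$l_h, 240)
  expect_equal(res$l_h_se, sd(c(200, 240, 280)) / sqrt(3), tolerance = 1e-9)
  expect_equal(res$l_h_se, 23.094, tolerance = 1e-4)

  single <- plot_litterfall(monthly_collections("t1"))
  expect_true(is.na(single$l_h_se))

  two_years <- dplyr::bind_rows(
    monthly_collections("t1", mass = 10, area = 0.5, year = 2019),
    monthly_collections("t1", mass = 260 / 24, area = 0.5, year = 2020)
  )
  expect_equal(plot_litterfall(two_years)$l_h, 250)
})

test_that("foliar production reconstructs the uneaten fraction", {
  expect_equal(foliar_production(200, 0), 200)
  expect_equal(foliar_production(200, 0.05), 210.5263, tolerance = 1e-4)
  expect_equal(foliar_production(300, 0.136), 347.2222, tolerance = 1e-4)
  expect_error(foliar_production(200, 1), "\\[0, 1\\)")
  expect_warning(foliar_production(200, 0.6), "0.5")
})

test_that("gross flux is the product of production, concentration and rate", {
  expect_equal(gross_flux(500, 0.02, 0), 0)
  expect_equal(gross_flux(500, 0.02, 0.05), 0.5)
  expect_equal(gross_flux(500, 0.48, 0.05), 12)
})

test_that("mass-loss correction depends on phenology", {
  expect_equal(mass_loss_correction("evergreen"), 0.78)
  expect_equal(mass_loss_correction("deciduous"), 0.784)
  expect_equal(mass_loss_correction(c("evergreen", "deciduous")),
               c(0.78, 0.784))
  expect_error(mass_loss_correction("mixed"), "phenology")
})

test_that("resorption efficiency corrects litter concentration for mass loss", {
  expect_equal(resorption_efficiency(0.02, 0.02, 1), 0)
  expect_equal(resorption_efficiency(0.02, 0.01, 0.784), 0.608)
  expect_equal(resorption_efficiency(0.02, 0.0107, 0.78), 1 - 0.535 * 0.78)
  expect_error(resorption_efficiency(0.004, 0.005, 0.78, element = "Si"),
               "Si")
  expect_warning(resorption_efficiency(0.01, 0.02, 0.784), "unclamped")
})

test_that("net flux is gross flux times resorption", {
  expect_equal(net_flux(0.5, 0), 0)
  expect_equal(net_flux(0.082, 0.618), 0.050676)
  expect_equal(net_flux(0.016, 0.579), 0.009264)
  expect_error(net_flux(0.1, 0.5, element = "Si"), "Si")
})

test_that("litter element fluxes and the counterfactual budget agree", {
  expect_equal(litter_element_flux(0, 0.01), 0)
  expect_equal(litter_element_flux(300, 0.01), 3)
  expect_equal(litter_element_flux(240, 0.005), 1.2)

  expect_equal(counterfactual_litter_flux(3, 500, 0, 0.01, 0.784), 3)
  expect_equal(counterfactual_litter_flux(4.75, 500, 0.05, 0.01, 0.784),
               4.946)

  expect_equal(hc_to_litter_ratio(1.5, 1.5), 1)
  expect_equal(hc_to_litter_ratio(0.03, 1.5), 0.02)
  expect_true(is.na(hc_to_litter_ratio(0.03, 0)))
})

test_that("the three-term budget identity holds for random inputs", {
  set.seed(42)
  n <- 1000
  l_h <- runif(n, 50, 800)
  h <- runif(n, 0, 0.45)
  f_green <- runif(n, 0.0005, 0.5)
  re <- runif(n, 0.01, 0.9)
  mlcf <- sample(c(0.78, 0.784), n, replace = TRUE)
  c_litter <- f_green * (1 - re) / mlcf
  fp <- foliar_production(l_h, h)
  h_c <- gross_flux(fp, f_green, h)
  l_eh <- litter_element_flux(l_h, c_litter)
  l_e <- counterfactual_litter_flux(l_eh, fp, h, c_litter, mlcf)
  h_i <- net_flux(h_c, re)
  expect_true(all(abs(l_eh + h_c - l_e - h_i) <=
                    1e-12 * pmax(1, abs(h_i))))
  expect_true(all(fp >= l_h))
  expect_true(all(fp[h == 0] == l_h[h == 0]))
  expect_equal(h_i / h_c, re, tolerance = 1e-12)
  expect_true(all(l_e >= l_eh))
})

test_that("doubling trap masses doubles fluxes but not rates", {
  base <- monthly_collections(mass = 10, area = 0.5)
  doubled <- dplyr::mutate(base, leaf_dry_mass = leaf_dry_mass * 2)
  l1 <- trap_annual_litterfall(base)
  l2 <- trap_annual_litterfall(doubled)
  expect_equal(l2, 2 * l1)
  h <- 0.04
  expect_equal(foliar_production(l2, h), 2 * foliar_production(l1, h))
  expect_equal(gross_flux(foliar_production(l2, h), 0.02, h),
               2 * gross_flux(foliar_production(l1, h), 0.02, h))
})

test_that("compute_fluxes produces a consistent per-plot-element table", {
  b <- tiny_bundle()
  fx <- compute_fluxes(b)
  expect_s3_class(fx, "flux_table")
  expect_equal(nrow(fx), 8) # 2 plots x 4 elements

  p1 <- fx[fx$plot_id == "p1" & fx$element == "N", ]
  # L_H = mean(240, 288) = 264; H = 0.015
  expect_equal(p1$l_h, 264)
  expect_equal(p1$h, 0.015)
  expect_equal(p1$fp, 264 / 0.985)
  expect_equal(p1$h_c, 264 / 0.985 * 0.02 * 0.015)
  expect_equal(p1$re, 1 - (0.011 / 0.02) * 0.78)
  expect_equal(p1$h_i, p1$h_c * p1$re)

  # Si rows carry gross flux only
  si <- fx[fx$element == "Si", ]
  expect_true(all(!is.na(si$h_c)))
  expect_true(all(is.na(si$re)) && all(is.na(si$h_i)))

  # row-wise invariants
  ok <- fx[!is.na(fx$h_i), ]
  expect_equal(ok$h_i, ok$h_c * ok$re)
  expect_true(all(fx$fp >= fx$l_h))
})

test_that("missing chemistry is a row-level error, not a failure", {
  b <- tiny_bundle()
  b$chemistry <- b$chemistry[!(b$chemistry$plot_id == "p2" &
                                 b$chemistry$element == "P"), ]
  fx <- compute_fluxes(b)
  bad <- fx[fx$plot_id == "p2" & fx$element == "P", ]
  expect_equal(bad$error, "missing chemistry")
  expect_true(is.na(bad$h_c))
  expect_true(all(is.na(fx$error[!(fx$plot_id == "p2" & fx$element == "P")])))
})
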