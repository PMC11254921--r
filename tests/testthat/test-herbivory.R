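test_that("class midpoints are the arithmetic midpoints of the class bounds", {
  expect_equal(class_midpoints(),
               c(0.005, 0.03, 0.15, 0.375, 0.625, 0.875))
  expect_equal(class_midpoints(damage_class_scheme(c(0, 1))), 0.5)
  expect_equal(
    class_midpoints(damage_class_scheme(c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1))),
    c(0.05, 0.15, 0.25, 0.35, 0.45, 0.75)
  )
  expect_error(damage_class_scheme(c(0, 0.5, 0.3, 1)), "increasing")
  expect_error(damage_class_scheme(c(0.1, 0.5, 1)), "start at 0")
})

test_that("herbivory rate is the midpoint-imputed mean leaf area removed", {
  expect_equal(herbivory_rate(rep(0, 6), n_undamaged = 30), 0)
  # (10*0.005 + 10*0.03 + 10*0.15) / 30
  expect_equal(herbivory_rate(c(10, 10, 10, 0, 0, 0)), 0.0616667,
               tolerance = 1e-5)
  expect_equal(herbivory_rate(c(0, 0, 0, 0, 0, 100)), 0.875)
  expect_error(herbivory_rate(rep(0, 6), n_undamaged = 0), "zero scored")
  expect_error(herbivory_rate(c(-1, 0, 0, 0, 0, 2)), "non-negative")
})

test_that("damage incidence is the fraction of leaves in any damage class", {
  expect_equal(damage_incidence(c(50, 0, 0, 0, 0, 0), n_undamaged = 50), 0.5)
  expect_equal(damage_incidence(rep(0, 6), n_undamaged = 30), 0)
  expect_equal(damage_incidence(c(100, 150, 150, 50, 30, 8),
                                n_undamaged = 512), 0.488)
})

test_that("pooling within a year is leaf-count weighted", {
  one <- tally_row(4, c(4, 1, 1, 0, 0, 0))   # H = 0.02, n = 10
  two <- tally_row(18, c(0, 0, 12, 0, 0, 0)) # H = 0.06, n = 30
  pooled <- pool_herbivory(dplyr::bind_rows(one, two))
  expect_equal(pooled$h, 0.05)
  expect_equal(pooled$n_leaves, 40)

  # duplicating a tally leaves H unchanged
  dup <- pool_herbivory(dplyr::bind_rows(one, one))
  expect_equal(dup$h, pool_herbivory(one)$h)

  # an all-zero tally is dropped with a warning
  empty <- tally_row(0, rep(0, 6))
  expect_warning(res <- pool_herbivory(dplyr::bind_rows(one, empty)),
                 "zero scored")
  expect_equal(res$h, pool_herbivory(one)$h)
})

test_that("annualization is an unweighted mean across years", {
  years <- tibble::tibble(h = c(0.04, 0.06), incidence = c(0.4, 0.5),
                          n_leaves = c(100, 10000))
  ann <- annualize_herbivory(years)
  expect_equal(ann$h, 0.05) # not the leaf-weighted 0.0598
  expect_equal(ann$incidence, 0.45)
  expect_equal(ann$n_leaves, 10100)
  one <- annualize_herbivory(years[1, ])
  expect_equal(one$h, 0.04)
  expect_error(annualize_herbivory(years[0, ]), "No yearly")
})

test_that("H is bounded by incidence and monotone in damage class", {
  scheme <- damage_class_scheme()
  mids <- scheme$midpoints
  set.seed(11)
  for (i in 1:50) {
    n_class <- as.numeric(rmultinom(1, 200, runif(6)))
    n_und <- rpois(1, 200)
    h <- herbivory_rate(n_class, n_und)
    inc <- damage_incidence(n_class, n_und)
    expect_lte(h, inc * max(mids) + 1e-12)
    # moving one leaf up a class never decreases H
    k <- sample(which(n_class > 0), 1)
    if (k < 6) {
      moved <- n_class
      moved[k] <- moved[k] - 1
      moved[k + 1] <- moved[k + 1] + 1
      expect_gte(herbivory_rate(moved, n_und), h)
    }
  }
  # all damage in one class: H = incidence * midpoint exactly
  for (k in 1:6) {
    n_class <- rep(0, 6); n_class[k] <- 37
    expect_equal(herbivory_rate(n_class, 63),
                 damage_incidence(n_class, 63) * mids[k])
  }
})

test_that("plot-level estimates pool scans within years then average years", {
  damage <- dplyr::bind_rows(
    tally_row(4, c(4, 1, 1, 0, 0, 0), scan_date = as.Date("2019-03-01")),
    tally_row(18, c(0, 0, 12, 0, 0, 0), scan_date = as.Date("2019-09-01")),
    tally_row(5, c(0, 5, 0, 0, 0, 0), scan_date = as.Date("2020-03-01"))
  )
  est <- estimate_herbivory(damage)
  # 2019 pooled H = 0.05; 2020 H = 0.015; annual mean 0.0325
  expect_equal(est$h, 0.0325)
  expect_equal(est$n_years, 2)
})
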