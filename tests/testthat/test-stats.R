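# brute-force Kruskal-Wallis oracle: rank formula with explicit tie
# correction, computed from first principles
kw_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction == 0) return(0)
  h / correction
}

test_that("transforms behave as log/logit with boundary handling", {
  x <- c(0.2, 0.5, 0.9)
  expect_identical(transform_values(x, "none"), x)
  expect_equal(transform_values(0.5, "logit"), 0)
  expect_equal(transform_values(c(1, exp(1), exp(2)), "log"), c(0, 1, 2))
  expect_error(transform_values(c(1, -1), "log"), "positive")
  expect_warning(out <- transform_values(c(0, 0.5, 1), "logit"), "eps")
  expect_equal(out[2], 0)
  expect_true(is.finite(out[1]) && is.finite(out[3]))
  expect_error(transform_values(c(0.5, 1.2), "logit"), "\\[0, 1\\]")
})

test_that("z-scores standardize and are affine-invariant", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  x <- rnorm(40)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(3 * x + 7), z, tolerance = 1e-12)
  expect_error(zscore(rep(2, 10)), "distinct")
})

test_that("VIF matches the closed form and screens collinearity", {
  # exactly orthogonal predictors
  a <- zscore(c(1, -1, 1, -1, 1, -1, 1, -1))
  b <- zscore(c(1, 1, -1, -1, 1, 1, -1, -1))
  v <- vif(data.frame(a = a, b = b))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-12)
  expect_true(attr(v, "all_pass"))

  # exact sample correlation 0.6 -> VIF = 1/(1 - 0.36)
  c_ <- zscore(c(1, -1, -1, 1, 1, -1, -1, 1))
  y <- 0.6 * a + 0.8 * c_
  v2 <- vif(data.frame(a = a, y = y))
  expect_equal(v2$vif, rep(1 / (1 - 0.36), 2), tolerance = 1e-9)
  expect_equal(v2$vif[1], 1.5625, tolerance = 1e-9)

  v3 <- vif(data.frame(a = a, b = b, dup = a))
  expect_false(attr(v3, "all_pass"))
  expect_true(any(!is.finite(v3$vif)))
})

test_that("mixed-model fit recovers exact and simulated slopes", {
  # noiseless y = x: standardized slope 1, residual variance ~ 0
  df <- tibble::tibble(
    x = zscore(seq_len(20)), y = zscore(seq_len(20)),
    site = rep(letters[1:10], each = 2)
  )
  fit <- suppressWarnings(fit_lmm(df, "y", "x", group = "site"))
  expect_equal(unname(lme4::fixef(fit$model)["x"]), 1, tolerance = 1e-6)
  expect_lt(fit$var_resid, 1e-10)
  # single-predictor noiseless limit: slope equals the Pearson correlation
  expect_equal(unname(lme4::fixef(fit$model)["x"]), cor(df$x, df$y),
               tolerance = 1e-6)

  # simulation with known standardized slope 0.6
  set.seed(123)
  n_site <- 50
  sim <- tibble::tibble(
    site = rep(sprintf("s%02d", 1:n_site), each = 2),
    x = rnorm(2 * n_site),
    y = 0.6 * x + rep(rnorm(n_site, 0, 0.5), each = 2) +
      rnorm(2 * n_site, 0, 0.5)
  )
  fit2 <- fit_lmm(sim, "y", "x", group = "site")
  est <- unname(lme4::fixef(fit2$model)["x"])
  se <- sqrt(diag(as.matrix(stats::vcov(fit2$model))))[2]
  expect_lt(abs(est - 0.6), 3 * se)
})

test_that("marginal and conditional R2 follow the variance components", {
  df <- tibble::tibble(
    x = zscore(seq_len(20)), y = zscore(seq_len(20)),
    site = rep(letters[1:10], each = 2)
  )
  # intercept-only model: marginal R2 is zero
  fit0 <- suppressWarnings(fit_lmm(df, "y", character(0), group = "site"))
  r20 <- r2_glmm(fit0)
  expect_equal(r20$r2_marginal, 0)

  # large simulation with known variances 1 (fixed), 1 (group), 2 (residual)
  set.seed(99)
  n_site <- 400
  sim <- tibble::tibble(
    site = rep(seq_len(n_site), each = 5),
    x = rnorm(5 * n_site),
    y = x + rep(rnorm(n_site, 0, 1), each = 5) +
      rnorm(5 * n_site, 0, sqrt(2))
  )
  fit <- fit_lmm(sim, "y", "x", group = "site")
  r2 <- r2_glmm(fit)
  expect_equal(r2$r2_marginal, 0.25, tolerance = 0.1)
  expect_equal(r2$r2_conditional, 0.50, tolerance = 0.1)

  # sum rule against the fitted components
  var_fixed <- stats::var(as.numeric(
    stats::model.matrix(fit$model) %*% lme4::fixef(fit$model)
  ))
  expect_equal(
    r2$r2_conditional - r2$r2_marginal,
    fit$var_group / (var_fixed + fit$var_group + fit$var_resid),
    tolerance = 1e-9
  )

  # a singular fit (zero estimated group variance): marginal equals
  # conditional exactly
  df2 <- tibble::tibble(
    x = zscore(seq_len(20)),
    y = zscore(seq_len(20)) + rep(c(-0.01, 0.01), 10),
    site = rep(letters[1:10], each = 2)
  )
  fit_ng <- suppressWarnings(fit_lmm(df2, "y", "x", group = "site"))
  if (fit_ng$var_group == 0) {
    r2ng <- r2_glmm(fit_ng)
    expect_equal(r2ng$r2_marginal, r2ng$r2_conditional)
  } else {
    # fall back to the asymptotic check on the large simulation
    sim0 <- dplyr::mutate(sim, y = x + rnorm(5 * n_site, 0, sqrt(2)))
    fit0g <- suppressWarnings(fit_lmm(sim0, "y", "x", group = "site"))
    r2ng <- r2_glmm(fit0g)
    expect_equal(r2ng$r2_marginal, r2ng$r2_conditional, tolerance = 0.05)
  }
})

test_that("parametric bootstrap is seed-deterministic and detects effects", {
  set.seed(321)
  sim <- tibble::tibble(
    site = rep(sprintf("s%02d", 1:50), each = 2),
    x = rnorm(100)
  )
  sim$y <- zscore(0.8 * sim$x + rep(rnorm(50, 0, 0.4), each = 2) +
                    rnorm(100, 0, 0.4))
  sim$x <- zscore(sim$x)
  fit <- fit_lmm(sim, "y", "x", group = "site")

  ci1 <- bootstrap_ci(fit, n_sim = 100, seed = 77)
  ci2 <- bootstrap_ci(fit, n_sim = 100, seed = 77)
  expect_identical(ci1, ci2)

  slope <- ci1[ci1$term == "x", ]
  expect_true(slope$significant)
  expect_gt(slope$ci_low, 0)
})

test_that("Kruskal-Wallis matches the published worked example and the oracle", {
  df <- tibble::tibble(v = 7, g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(df, "v", "g")$chi_square, 0)
  expect_equal(kruskal_wallis(df, "v", "g")$p_value, 1)

  sep <- tibble::tibble(v = 1:9, g = rep(c("a", "b", "c"), each = 3))
  kt <- kruskal_wallis(sep, "v", "g")
  expect_equal(kt$chi_square, 7.2)
  expect_equal(kt$df, 2)
  expect_equal(kt$chi_square, kw_oracle(sep$v, sep$g))

  # rank invariance under strictly increasing transforms
  expect_equal(kruskal_wallis(dplyr::mutate(sep, v = exp(v)), "v", "g")$chi_square,
               7.2)

  # tied data against the oracle
  set.seed(14)
  for (i in 1:25) {
    v <- sample(1:5, 15, replace = TRUE)
    g <- rep(c("a", "b", "c"), each = 5)
    expect_equal(kruskal_wallis(tibble::tibble(v = v, g = g), "v", "g")$chi_square,
                 kw_oracle(v, g), tolerance = 1e-12)
  }
})

test_that("Dunn post-hoc flags separated groups and adjusts p upward", {
  same <- tibble::tibble(v = rep(c(1, 2, 3), 3),
                         g = rep(c("a", "b", "c"), each = 3))
  gt <- dunn_posthoc(same, "v", "g")
  expect_true(all(gt$pairwise$p_adjusted == 1))
  expect_true(all(gt$letters == "a")) # one shared letter

  set.seed(6)
  sepd <- tibble::tibble(
    v = c(rnorm(10), rnorm(10, 10), rnorm(10, 20)),
    g = rep(c("a", "b", "c"), each = 10)
  )
  gt2 <- dunn_posthoc(sepd, "v", "g")
  expect_true(all(gt2$pairwise$p_adjusted < 0.05))
  expect_equal(unname(gt2$letters), c("a", "b", "c")) # all distinct
  expect_true(all(gt2$pairwise$p_adjusted >= gt2$pairwise$p))

  gt3 <- dunn_posthoc(sepd, "v", "g", adjustment = "bonferroni")
  expect_equal(gt3$pairwise$p_adjusted,
               pmin(1, gt3$pairwise$p * 3), tolerance = 1e-12)
})

test_that("driver analysis runs transform -> zscore -> VIF -> fit -> bootstrap", {
  b <- generate_network(synthetic_config(n_sites = 15, h_mat_slope = 0.6),
                        seed = 31)
  fx <- suppressWarnings(compute_fluxes(b, elements = "N"))
  frame <- fx |>
    dplyr::filter(is.na(error)) |>
    dplyr::distinct(plot_id, site_id, h) |>
    dplyr::left_join(dplyr::select(b$plots, plot_id, mat, dryness),
                     by = "plot_id")
  res <- driver_analysis(frame, responses = "h",
                         predictors = c("mat", "dryness"),
                         bootstrap_n = 100, seed = 9)
  expect_setequal(res$predictor, c("mat", "dryness"))
  mat_row <- res[res$predictor == "mat", ]
  expect_gt(mat_row$estimate, 0)
  expect_true(mat_row$significant)
  expect_true(all(res$r2_marginal <= res$r2_conditional))

  expect_error(
    driver_analysis(dplyr::mutate(frame, mat2 = mat), responses = "h",
                    predictors = c("mat", "mat2"), bootstrap_n = 20),
    "VIF"
  )
})
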