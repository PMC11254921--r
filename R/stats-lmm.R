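#' Random-intercept linear mixed model with standardized coefficients
#'
#' Fits a Gaussian linear mixed model by restricted maximum likelihood with
#' a random intercept per group (site, or site:plot when plots contribute
#' multiple rows), via [lme4::lmer()]. Variables are expected to be
#' transformed and z-scored already (see [transform_values()], [zscore()]
#' and [driver_analysis()], which applies transform, z-score and VIF
#' screening in order), so fixed-effect estimates are standardized
#' coefficients. A singular fit (group variance estimated at zero) is
#' returned with a warning rather than an error.
#'
#' @param data Model frame (one row per observation).
#' @param response Response column name.
#' @param predictors Character vector of fixed-effect column names; empty
#'   for an intercept-only model.
#' @param group Grouping column name for the random intercept.
#' @return An object of class `herbivory_lmm` with methods [tidy()],
#'   [glance()] and [r2_glmm()].
#' @export
fit_lmm <- function(data, response, predictors, group = "site_id") {
  data <- as_tibble(data)
  missing <- setdiff(c(response, predictors, group), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing model columns: ", paste(missing, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[c(response, predictors, group)]), ]
  rhs <- if (length(predictors) == 0) "1" else
    paste(sprintf("`%s`", predictors), collapse = " + ")
  fml <- stats::as.formula(
    sprintf("`%s` ~ %s + (1 | `%s`)", response, rhs, group)
  )
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    message = function(m) invokeRestart("muffleMessage")
  )
  if (lme4::isSingular(fit)) {
    warn("Singular fit: random-intercept variance estimated at zero.")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_group <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  structure(
    list(
      model = fit,
      response = response,
      predictors = predictors,
      group = group,
      n_obs = nrow(data),
      n_groups = length(unique(data[[group]])),
      var_group = var_group,
      var_resid = var_resid
    ),
    class = "herbivory_lmm"
  )
}

#' @method print herbivory_lmm
#' @export
print.herbivory_lmm <- function(x, ...) {
  cat(sprintf("<herbivory_lmm> %s ~ %s + (1 | %s)\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$group))
  cat(sprintf("  %d obs in %d groups; var(group) = %.4g, var(resid) = %.4g\n",
              x$n_obs, x$n_groups, x$var_group, x$var_resid))
  r2 <- r2_glmm(x)
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
              r2$r2_marginal, r2$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-components goodness of fit: the marginal R2 is the variance of
#' the fixed-effect linear predictor over the total (fixed + random
#' intercept + residual) variance; the conditional R2 adds the random
#' intercept variance to the numerator.
#'
#' @param fit A `herbivory_lmm` from [fit_lmm()].
#' @return A one-row tibble with `r2_marginal` and `r2_conditional`.
#' @export
r2_glmm <- function(fit) {
  stopifnot(inherits(fit, "herbivory_lmm"))
  eta <- as.numeric(
    stats::model.matrix(fit$model) %*% lme4::fixef(fit$model)
  )
  var_fixed <- if (length(eta) < 2) 0 else stats::var(eta)
  total <- var_fixed + fit$var_group + fit$var_resid
  tibble(
    r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + fit$var_group) / total
  )
}

#' Parametric-bootstrap confidence intervals for fixed effects
#'
#' Simulates new responses from the fitted Gaussian mixed model, refits, and
#' takes percentile intervals of the fixed-effect estimates. An effect is
#' flagged significant when its interval excludes zero. Identical seeds give
#' identical intervals; the run errors if more than 5% of refits fail.
#'
#' @param fit A `herbivory_lmm` from [fit_lmm()].
#' @param n_sim Number of bootstrap simulations (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the simulation stream.
#' @return A tibble with `term`, `estimate`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
bootstrap_ci <- function(fit, n_sim = 1000, level = 0.95, seed = 20240717) {
  stopifnot(inherits(fit, "herbivory_lmm"))
  boo <- suppressWarnings(suppressMessages(
    lme4::bootMer(fit$model, FUN = lme4::fixef, nsim = n_sim,
                  seed = seed, type = "parametric", use.u = FALSE)
  ))
  draws <- boo$t
  failed <- apply(draws, 1, function(r) any(!is.finite(r)))
  if (mean(failed) > 0.05) {
    abort(sprintf("%.1f%% of bootstrap refits failed (> 5%%).",
                  100 * mean(failed)))
  }
  draws <- draws[!failed, , drop = FALSE]
  alpha <- (1 - level) / 2
  est <- lme4::fixef(fit$model)
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  tibble(
    term = names(est),
    estimate = as.numeric(est),
    ci_low = qs[1, ],
    ci_high = qs[2, ],
    significant = qs[1, ] > 0 | qs[2, ] < 0
  )
}

#' @export
tidy.herbivory_lmm <- function(x, ci = NULL, ...) {
  est <- lme4::fixef(x$model)
  out <- tibble(term = names(est), estimate = as.numeric(est))
  if (!is.null(ci)) out <- left_join(out, ci[setdiff(names(ci), "estimate")],
                                     by = "term")
  out
}

#' @export
glance.herbivory_lmm <- function(x, ...) {
  bind_cols(
    tibble(
      response = x$response, n_obs = x$n_obs, n_groups = x$n_groups,
      var_group = x$var_group, var_resid = x$var_resid
    ),
    r2_glmm(x)
  )
}
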