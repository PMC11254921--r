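#' Default transform assignment for model variables
#'
#' Fluxes, production and concentrations are log transformed; proportions
#' (herbivory rate, incidence, resorption efficiency) are logit transformed;
#' climate and stoichiometry variables stay untransformed unless their
#' skewness exceeds 2 and they are strictly positive, in which case they are
#' log transformed.
#'
#' @param name Variable name.
#' @param values The variable's values (used for the skewness fallback).
#' @return `"none"`, `"log"` or `"logit"`.
#' @keywords internal
default_transform <- function(name, values) {
  logit_vars <- c("h", "incidence", "re")
  log_vars <- c("fp", "l_h", "h_c", "h_i", "l_eh", "l_e", "f_green",
                "c_litter", "s_c", "s_n", "s_p", "s_si")
  base <- sub("_[CNPS][a-z]*$", "", name)
  if (name %in% logit_vars || base %in% logit_vars) return("logit")
  if (name %in% log_vars || base %in% log_vars) return("log")
  if (skewness(values) > 2 && all(values > 0, na.rm = TRUE)) return("log")
  "none"
}

prepare_model_frame <- function(data, vars, transforms = NULL, eps = 1e-4) {
  for (v in vars) {
    kind <- transforms[[v]] %||% default_transform(v, data[[v]])
    data[[v]] <- zscore(transform_values(data[[v]], kind, eps = eps))
  }
  data
}

#' Mixed-model driver analysis of insect-mediated fluxes
#'
#' Fits the standard two model families used to explain plot-level flux
#' variation: *simple* models (one fixed predictor + random site intercept,
#' one fit per response x predictor pair) and *full* models (all predictors
#' + random site intercept, after VIF screening). For every model the
#' workflow is transform (log/logit as assigned by [default_transform()] or
#' overridden), z-score, VIF screen (full models), REML fit, then
#' parametric-bootstrap confidence intervals; effects whose interval
#' excludes zero are flagged significant.
#'
#' @param data One row per plot, containing the response and predictor
#'   columns plus the grouping column.
#' @param responses Character vector of response column names.
#' @param predictors Character vector of fixed-effect column names.
#' @param group Grouping column for the random intercept (default site).
#' @param mode `"full"`, `"simple"` or `"both"`.
#' @param transforms Optional named list overriding transform kinds per
#'   variable.
#' @param bootstrap_n Parametric-bootstrap simulations per model.
#' @param level Confidence level.
#' @param seed Seed for the bootstrap stream.
#' @param vif_threshold VIF screening threshold for full models.
#' @return A tibble of class `driver_results`: one row per response x
#'   predictor x model type with `estimate`, `ci_low`, `ci_high`,
#'   `significant`, `r2_marginal`, `r2_conditional`, `n_obs`, `n_groups`.
#'   Fitted models are attached as attribute `fits`.
#' @export
driver_analysis <- function(data, responses, predictors, group = "site_id",
                            mode = c("full", "simple", "both"),
                            transforms = NULL, bootstrap_n = 1000,
                            level = 0.95, seed = 20240717,
                            vif_threshold = 2) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  missing <- setdiff(c(responses, predictors, group), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }

  specs <- list()
  if (mode %in% c("simple", "both")) {
    for (r in responses) for (p in predictors) {
      specs[[length(specs) + 1]] <- list(response = r, predictors = p,
                                         type = "simple")
    }
  }
  if (mode %in% c("full", "both")) {
    for (r in responses) {
      specs[[length(specs) + 1]] <- list(response = r, predictors = predictors,
                                         type = "full")
    }
  }

  fits <- list()
  rows <- purrr::imap_dfr(specs, function(sp, i) {
    cols <- c(sp$response, sp$predictors, group)
    frame <- data[stats::complete.cases(data[cols]), cols]
    frame <- prepare_model_frame(frame, c(sp$response, sp$predictors),
                                 transforms = transforms)
    if (sp$type == "full" && length(sp$predictors) > 1) {
      screen <- vif(frame[sp$predictors], threshold = vif_threshold)
      if (!attr(screen, "all_pass")) {
        abort(paste0(
          "VIF screening failed for response '", sp$response, "': ",
          paste(sprintf("%s = %.3g", screen$predictor[!screen$pass],
                        screen$vif[!screen$pass]), collapse = ", ")
        ))
      }
    }
    fit <- suppressWarnings(
      fit_lmm(frame, sp$response, sp$predictors, group = group)
    )
    ci <- bootstrap_ci(fit, n_sim = bootstrap_n, level = level,
                       seed = seed + i)
    fits[[paste(sp$type, sp$response, sep = ".")]] <<- fit
    r2 <- r2_glmm(fit)
    ci |>
      filter(.data$term != "(Intercept)") |>
      mutate(
        response = sp$response, model = sp$type,
        predictor = gsub("`", "", .data$term),
        r2_marginal = r2$r2_marginal, r2_conditional = r2$r2_conditional,
        n_obs = fit$n_obs, n_groups = fit$n_groups
      ) |>
      select("response", "model", "predictor", "estimate", "ci_low",
             "ci_high", "significant", "r2_marginal", "r2_conditional",
             "n_obs", "n_groups")
  })
  attr(rows, "fits") <- fits
  class(rows) <- c("driver_results", class(rows))
  rows
}
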