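#' Log and logit transforms for response variables
#'
#' Flux-like variables are log transformed and proportion-like variables
#' (herbivory rate, resorption efficiency) are logit transformed before
#' z-scoring and model fitting. Exact 0 or 1 under the logit is shifted
#' inward by `eps` (default 1e-4, half the smallest resolution of the
#' visual damage scores) with a warning.
#'
#' @param x Numeric vector.
#' @param kind `"none"`, `"log"` or `"logit"`.
#' @param eps Boundary adjustment for the logit.
#' @return Transformed vector.
#' @examples
#' transform_values(c(1, exp(1), exp(2)), "log")
#' transform_values(0.5, "logit")
#' @export
transform_values <- function(x, kind = c("none", "log", "logit"), eps = 1e-4) {
  kind <- match.arg(kind)
  if (kind == "none") return(x)
  if (kind == "log") {
    if (any(x <= 0, na.rm = TRUE)) {
      abort("Log transform requires strictly positive values.")
    }
    return(log(x))
  }
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort("Logit transform requires values in [0, 1].")
  }
  at_bound <- !is.na(x) & (x == 0 | x == 1)
  if (any(at_bound)) {
    warn(sprintf("%d value(s) at 0 or 1 shifted by eps = %g before logit.",
                 sum(at_bound), eps))
    x[!is.na(x) & x == 0] <- eps
    x[!is.na(x) & x == 1] <- 1 - eps
  }
  log(x / (1 - x))
}

#' Standardize to z-scores
#'
#' Centers and scales to sample mean 0 and sample standard deviation 1.
#' All variables entering the mixed models are z-scored so fixed-effect
#' estimates are standardized coefficients comparable across predictors.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return Standardized vector.
#' @export
zscore <- function(x) {
  ok <- x[!is.na(x)]
  if (length(unique(ok)) < 2) {
    abort("z-scoring requires at least two distinct values.")
  }
  (x - mean(ok)) / stats::sd(ok)
}

#' Variance inflation factors
#'
#' Screens a predictor set for multicollinearity: each predictor is
#' regressed on the others and VIF_j = 1 / (1 - R2_j). Screening passes only
#' if every VIF is below `threshold` (default 2); perfectly collinear
#' predictors give infinite VIF and fail.
#'
#' @param data Data frame of numeric predictors (columns are screened).
#' @param predictors Optional character vector naming the columns to screen
#'   (default: all columns).
#' @param threshold Pass threshold.
#' @return A tibble with `predictor`, `vif` and `pass`; attribute
#'   `all_pass`.
#' @examples
#' vif(data.frame(a = rnorm(20), b = rnorm(20)))
#' @export
vif <- function(data, predictors = NULL, threshold = 2) {
  data <- as_tibble(data)
  if (!is.null(predictors)) data <- data[predictors]
  if (ncol(data) < 2) abort("VIF screening needs at least two predictors.")
  if (nrow(data) <= ncol(data)) {
    abort("VIF screening needs more observations than predictors.")
  }
  out <- purrr::map_dbl(names(data), function(j) {
    fit <- stats::lm(
      stats::reformulate(sprintf("`%s`", setdiff(names(data), j)),
                         response = sprintf("`%s`", j)),
      data = data
    )
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  res <- tibble(predictor = names(data), vif = out,
                pass = is.finite(out) & out < threshold)
  attr(res, "all_pass") <- all(res$pass)
  res
}
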