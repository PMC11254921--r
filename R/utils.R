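#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# standard error of the mean; NA for n < 2 (a single trap or plot carries no
# dispersion information)
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# moment skewness, used only to decide default transforms
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
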