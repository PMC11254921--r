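#' Damage-class scheme for visual herbivory scoring
#'
#' Litter leaves are scored into an undamaged class plus six ordered classes
#' of leaf area removed. The default boundaries follow the standard visual
#' scoring protocol for broadleaved litter: 0--1%, 1--5%, 5--25%, 25--50%,
#' 50--75% and >75% of leaf area removed. Herbivory rate is estimated by
#' midpoint imputation within each class, so the scheme carries both the
#' class bounds and their arithmetic midpoints.
#'
#' @param bounds Strictly increasing numeric vector of class boundaries as
#'   fractions of leaf area, starting at 0 and ending at 1. Length `k + 1`
#'   for `k` classes (default 7 values, 6 classes).
#' @return An object of class `damage_class_scheme`: a list with `bounds`
#'   and `midpoints`.
#' @examples
#' scheme <- damage_class_scheme()
#' class_midpoints(scheme)
#' @export
damage_class_scheme <- function(bounds = c(0, 0.01, 0.05, 0.25, 0.50, 0.75, 1)) {
  bounds <- as.numeric(bounds)
  if (length(bounds) < 2 || anyNA(bounds)) {
    abort("`bounds` must be a numeric vector of at least 2 class boundaries.")
  }
  if (any(diff(bounds) <= 0)) {
    abort("`bounds` must be strictly increasing.")
  }
  if (bounds[1] != 0 || bounds[length(bounds)] != 1) {
    abort("`bounds` must start at 0 and end at 1 (fractions of leaf area).")
  }
  structure(
    list(
      bounds = bounds,
      midpoints = (bounds[-length(bounds)] + bounds[-1]) / 2
    ),
    class = "damage_class_scheme"
  )
}

#' @rdname damage_class_scheme
#' @param scheme A `damage_class_scheme`.
#' @export
class_midpoints <- function(scheme = damage_class_scheme()) {
  if (!inherits(scheme, "damage_class_scheme")) {
    scheme <- damage_class_scheme(scheme)
  }
  scheme$midpoints
}

n_classes <- function(scheme) length(scheme$midpoints)

check_tally <- function(n_class, n_undamaged, scheme) {
  if (length(n_class) != n_classes(scheme)) {
    abort(sprintf(
      "`n_class` has %d counts but the scheme defines %d damage classes.",
      length(n_class), n_classes(scheme)
    ))
  }
  if (any(n_class < 0) || n_undamaged < 0) {
    abort("Damage-class counts must be non-negative.")
  }
  total <- n_undamaged + sum(n_class)
  if (total <= 0) {
    abort("Tally has zero scored leaves; herbivory rate is undefined.")
  }
  total
}

#' Herbivory rate and damage incidence from a leaf-damage tally
#'
#' `herbivory_rate()` estimates the mean proportion of leaf area removed per
#' leaf, H, from counts of leaves per damage class: each damaged leaf is
#' imputed the midpoint of its class and undamaged leaves contribute zero,
#' so \eqn{H = \sum_k n_k m_k / N} with \eqn{N} the total scored leaves.
#' `damage_incidence()` is the fraction of scored leaves placed in any
#' damage class.
#'
#' @param n_class Numeric vector of counts of damaged leaves per class
#'   (length must match the scheme, default 6).
#' @param n_undamaged Count of leaves with no recorded damage.
#' @param scheme A [damage_class_scheme()].
#' @return A single fraction.
#' @examples
#' herbivory_rate(c(10, 10, 10, 0, 0, 0), n_undamaged = 0)
#' damage_incidence(c(0, 488, 0, 0, 0, 0), n_undamaged = 512)
#' @export
herbivory_rate <- function(n_class, n_undamaged = 0,
                           scheme = damage_class_scheme()) {
  total <- check_tally(n_class, n_undamaged, scheme)
  sum(n_class * scheme$midpoints) / total
}

#' @rdname herbivory_rate
#' @export
damage_incidence <- function(n_class, n_undamaged = 0,
                             scheme = damage_class_scheme()) {
  total <- check_tally(n_class, n_undamaged, scheme)
  sum(n_class) / total
}

damage_count_cols <- function(scheme) paste0("n_c", seq_len(n_classes(scheme)))

#' Pool leaf-damage tallies within a plot-year
#'
#' Scans within a year are pooled by summing leaf counts before computing H
#' and incidence (leaf-weighted pooling), so scans that scored more leaves
#' carry proportionally more weight. Tallies with zero scored leaves are
#' dropped with a warning.
#'
#' @param damage A data frame of tallies for one plot-year with columns
#'   `n_undamaged` and `n_c1` ... `n_c6` (one row per scan).
#' @param scheme A [damage_class_scheme()].
#' @return A one-row tibble with `h`, `incidence` and `n_leaves`.
#' @examples
#' scans <- tibble::tibble(
#'   n_undamaged = c(90, 80),
#'   n_c1 = c(5, 10), n_c2 = c(5, 10), n_c3 = 0,
#'   n_c4 = 0, n_c5 = 0, n_c6 = 0
#' )
#' pool_herbivory(scans)
#' @export
pool_herbivory <- function(damage, scheme = damage_class_scheme()) {
  cols <- damage_count_cols(scheme)
  missing <- setdiff(c("n_undamaged", cols), names(damage))
  if (length(missing) > 0) {
    abort(paste0("`damage` is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(damage) == 0) abort("No tallies supplied.")
  totals <- damage$n_undamaged + rowSums(damage[cols])
  if (any(totals == 0)) {
    warn(sprintf("Dropping %d tally row(s) with zero scored leaves.",
                 sum(totals == 0)))
    damage <- damage[totals > 0, , drop = FALSE]
  }
  if (nrow(damage) == 0) abort("All tallies have zero scored leaves.")
  n_class <- colSums(damage[cols])
  n_undamaged <- sum(damage$n_undamaged)
  tibble(
    h = herbivory_rate(n_class, n_undamaged, scheme),
    incidence = damage_incidence(n_class, n_undamaged, scheme),
    n_leaves = n_undamaged + sum(n_class)
  )
}

#' Annualize herbivory estimates across collection years
#'
#' When a plot contributes two years of scans, the plot-level H and
#' incidence are the unweighted means of the yearly values (an annual mean,
#' not a leaf-weighted mean, so a heavily sampled year does not dominate);
#' `n_leaves` is the total scored.
#'
#' @param year_estimates A data frame with one row per year and columns
#'   `h`, `incidence` and `n_leaves` (as returned by [pool_herbivory()]).
#' @return A one-row tibble with `h`, `incidence`, `n_leaves` and `n_years`.
#' @export
annualize_herbivory <- function(year_estimates) {
  if (nrow(year_estimates) == 0) abort("No yearly estimates supplied.")
  tibble(
    h = mean(year_estimates$h),
    incidence = mean(year_estimates$incidence),
    n_leaves = sum(year_estimates$n_leaves),
    n_years = nrow(year_estimates)
  )
}

#' Plot-level herbivory estimates from a damage table
#'
#' Pools scans within each plot-year (leaf-weighted), then averages across
#' years (unweighted), returning one row per plot.
#'
#' @param damage A damage table with columns `plot_id`, `scan_date`,
#'   `n_undamaged`, `n_c1` ... `n_c6`.
#' @param scheme A [damage_class_scheme()].
#' @return A tibble with columns `plot_id`, `h`, `incidence`, `n_leaves`,
#'   `n_years`.
#' @export
estimate_herbivory <- function(damage, scheme = damage_class_scheme()) {
  if (!all(c("plot_id", "scan_date") %in% names(damage))) {
    abort("`damage` must have `plot_id` and `scan_date` columns.")
  }
  damage |>
    mutate(.year = format(as.Date(.data$scan_date), "%Y")) |>
    group_by(.data$plot_id, .data$.year) |>
    group_modify(~ pool_herbivory(.x, scheme)) |>
    group_by(.data$plot_id) |>
    group_modify(~ annualize_herbivory(.x)) |>
    ungroup()
}
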