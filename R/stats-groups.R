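#' Kruskal-Wallis rank test across groups
#'
#' Rank-based k-sample test with tie correction (via
#' [stats::kruskal.test()]), used for zone contrasts of plot-level
#' variables. With all values identical the statistic is 0 and p = 1.
#'
#' @param data Data frame.
#' @param value Name of the value column.
#' @param group Name of the grouping column.
#' @return An object of class `group_test` with `chi_square`, `df`,
#'   `p_value` and (after [dunn_posthoc()]) a `pairwise` table.
#' @examples
#' kruskal_wallis(
#'   data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3)),
#'   "v", "g"
#' )
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- data[[value]]
  g <- as.factor(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Kruskal-Wallis needs at least two groups.")
  if (length(unique(v)) == 1) {
    res <- list(chi_square = 0, df = nlevels(g) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(v, g)
    res <- list(
      chi_square = unname(kt$statistic),
      df = unname(kt$parameter),
      p_value = kt$p.value
    )
  }
  structure(
    c(res, list(value = value, group = group, data = tibble(value = v, group = g))),
    class = "group_test"
  )
}

#' @method print group_test
#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> Kruskal-Wallis chi-square = %.4g, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Dunn pairwise comparisons:\n")
    print(as.data.frame(x$pairwise))
  }
  invisible(x)
}

#' @export
glance.group_test <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value)
}

#' @export
tidy.group_test <- function(x, ...) {
  if (is.null(x$pairwise)) glance(x) else x$pairwise
}

# mean ranks and the tie-corrected Dunn variance term
dunn_z <- function(v, g) {
  N <- length(v)
  r <- rank(v)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  levels_g <- names(mean_ranks)
  pairs <- utils::combn(levels_g, 2)
  z <- apply(pairs, 2, function(p) {
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) *
                    (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) / sigma
  })
  tibble(
    group_a = pairs[1, ], group_b = pairs[2, ],
    z = as.numeric(z), p = 2 * stats::pnorm(-abs(z))
  )
}

# compact letter display: maximal cliques of the "not significantly
# different" graph each receive one letter (Bron-Kerbosch, fine for the
# handful of zones compared here)
cld_letters <- function(groups, pairwise, alpha = 0.05) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  sig <- pairwise[pairwise$p_adjusted < alpha, ]
  for (i in seq_len(nrow(sig))) {
    adj[sig$group_a[i], sig$group_b[i]] <- FALSE
    adj[sig$group_b[i], sig$group_a[i]] <- FALSE
  }
  cliques <- list()
  bron_kerbosch <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      cliques[[length(cliques) + 1]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- groups[adj[v, ] & groups != v]
      bron_kerbosch(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bron_kerbosch(character(0), groups, character(0))
  letters_out <- stats::setNames(rep("", k), groups)
  for (i in seq_along(cliques)) {
    for (gname in cliques[[i]]) {
      letters_out[gname] <- paste0(letters_out[gname], letters[i])
    }
  }
  letters_out
}

#' Dunn pairwise post-hoc comparisons
#'
#' Follows a Kruskal-Wallis test with pairwise z statistics from mean-rank
#' differences using the tie-corrected variance, adjusted for multiplicity
#' by the Holm (default) or Bonferroni method. Also derives a compact
#' letter display: groups not significantly different share a letter.
#'
#' @param x A `group_test` from [kruskal_wallis()], or a data frame (then
#'   `value` and `group` must be given).
#' @param value,group Column names when `x` is a data frame.
#' @param adjustment `"holm"` or `"bonferroni"`.
#' @param alpha Significance level for the letter display.
#' @return The `group_test` with a `pairwise` tibble (`group_a`, `group_b`,
#'   `z`, `p`, `p_adjusted`) and a `letters` vector attached.
#' @export
dunn_posthoc <- function(x, value = NULL, group = NULL,
                         adjustment = c("holm", "bonferroni"), alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  if (!inherits(x, "group_test")) {
    x <- kruskal_wallis(x, value, group)
  }
  d <- x$data
  empty <- levels(d$group)[tabulate(d$group, nlevels(d$group)) == 0]
  if (length(empty) > 0) {
    warn(paste0("Excluding empty group(s): ", paste(empty, collapse = ", ")))
    d$group <- droplevels(d$group)
  }
  pw <- dunn_z(d$value, d$group)
  pw$p_adjusted <- stats::p.adjust(pw$p, method = adjustment)
  x$pairwise <- pw
  x$adjustment <- adjustment
  x$letters <- cld_letters(levels(d$group), pw, alpha = alpha)
  x
}
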