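#' Run the full herbivory-flux pipeline
#'
#' Orchestrates read/validate, herbivory and litterfall estimation, flux
#' accounting, zone summaries, reference comparisons, zone contrasts
#' (Kruskal-Wallis + Dunn) and the mixed-model driver analysis, and writes
#' the result tables as CSV. All stochastic steps (the bootstrap; the
#' generator, if a synthetic dataset is requested) flow from `seed`, so a
#' rerun with the same inputs is identical.
#'
#' @param x A [forest_bundle()], a directory containing the CSV bundle, or
#'   the path of a YAML config file with keys `dataset` (directory, or
#'   `"synthetic"`), `elements`, `bootstrap_n`, `adjustment`, `seed`,
#'   `damage_class_bounds` and (for synthetic data) any
#'   [synthetic_config()] fields.
#' @param out Output directory; created if needed. `NULL` skips writing.
#' @param elements Elements to account for.
#' @param bootstrap_n Parametric-bootstrap simulations per model.
#' @param adjustment Dunn p-adjustment, `"holm"` or `"bonferroni"`.
#' @param seed Seed for all stochastic steps.
#' @param scheme A [damage_class_scheme()].
#' @param drivers Run the (slow) mixed-model driver analysis.
#' @return A list of class `herbflux_run` with elements `fluxes`,
#'   `summaries`, `comparisons`, `tests`, `letters`, `models`, `validation`
#'   and `log`.
#' @export
run_all <- function(x, out = NULL, elements = c("C", "N", "P", "Si"),
                    bootstrap_n = 1000, adjustment = "holm",
                    seed = 20240717, scheme = damage_class_scheme(),
                    drivers = TRUE) {
  if (is.character(x) && length(x) == 1 && grepl("\\.ya?ml$", x)) {
    # keep bare Y/N element symbols as strings rather than YAML 1.1 booleans
    cfg <- yaml::read_yaml(x, handlers = list(
      "bool#yes" = function(v) v, "bool#no" = function(v) v
    ))
    if (!is.null(cfg$damage_class_bounds)) {
      scheme <- damage_class_scheme(as.numeric(cfg$damage_class_bounds))
    }
    elements <- as.character(unlist(cfg$elements %||% elements))
    bootstrap_n <- cfg$bootstrap_n %||% bootstrap_n
    adjustment <- cfg$adjustment %||% adjustment
    seed <- cfg$seed %||% seed
    if (identical(cfg$dataset, "synthetic")) {
      gen_args <- cfg[intersect(names(cfg), names(formals(synthetic_config)))]
      x <- generate_network(do.call(synthetic_config, gen_args), seed = seed,
                            scheme = scheme)
    } else {
      x <- cfg$dataset
    }
  }
  bundle <- if (inherits(x, "forest_bundle")) x else read_dataset(x)

  log_lines <- c(
    sprintf("elements: %s", paste(elements, collapse = ",")),
    sprintf("damage class midpoints: %s",
            paste(signif(scheme$midpoints, 4), collapse = ", ")),
    sprintf("mass-loss correction: evergreen 0.78, deciduous 0.784"),
    sprintf("bootstrap_n: %d; adjustment: %s; seed: %d",
            bootstrap_n, adjustment, seed)
  )

  validation <- validate_dataset(bundle)
  fatal <- validation[!startsWith(validation$message, "warning:"), ]
  if (nrow(fatal) > 0) {
    abort(paste0(
      "Dataset failed validation; first finding: ",
      sprintf("[%s %s] %s: %s", fatal$table[1], fatal$record[1],
              fatal$field[1], fatal$message[1])
    ))
  }
  log_lines <- c(log_lines, sprintf(
    "validation: ok (%d non-fatal warning finding(s))", nrow(validation)
  ))

  fluxes <- compute_fluxes(bundle, elements = elements, scheme = scheme)
  excluded <- fluxes |> filter(!is.na(.data$error))
  if (nrow(excluded) > 0) {
    log_lines <- c(log_lines, sprintf(
      "excluded plot/element rows: %s",
      paste(sprintf("%s/%s (%s)", excluded$plot_id, excluded$element,
                    excluded$error), collapse = "; ")
    ))
  }

  wide <- flux_wide(fluxes)
  summary_vars <- intersect(
    c("fp", "h", outer(c("h_c_", "h_i_"), elements, paste0)),
    names(wide)
  )
  summaries <- zone_summaries(wide, dplyr::all_of(summary_vars))
  comparisons <- if (all(c("N", "P") %in% elements)) {
    compare_references(fluxes, bundle$references)
  } else {
    tibble()
  }

  tests <- purrr::map_dfr(summary_vars, function(v) {
    if (length(unique(wide$zone[!is.na(wide[[v]])])) < 2) return(tibble())
    gt <- dunn_posthoc(wide[!is.na(wide[[v]]), ], v, "zone",
                       adjustment = adjustment)
    bind_cols(tibble(variable = v), glance(gt)) |>
      mutate(letters = paste(
        sprintf("%s=%s", names(gt$letters), gt$letters), collapse = ";"
      ))
  })
  letters_tbl <- tests |> select("variable", "letters")

  models <- NULL
  if (drivers) {
    responses <- intersect(
      c("fp", "h", paste0("h_c_", elements),
        paste0("h_i_", setdiff(elements, "Si"))),
      names(wide)
    )
    frame <- wide |>
      left_join(bundle$soil, by = "plot_id") |>
      left_join(bundle$plots |> select("plot_id", "mat", "dryness"),
                by = "plot_id")
    models <- driver_analysis(
      frame, responses = responses,
      predictors = c("mat", "dryness", "s_cn"),
      group = "site_id", mode = "full",
      bootstrap_n = bootstrap_n, seed = seed
    )
  }

  result <- structure(
    list(
      fluxes = fluxes, summaries = summaries, comparisons = comparisons,
      tests = tests, letters = letters_tbl, models = models,
      validation = validation, log = log_lines
    ),
    class = "herbflux_run"
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_fluxes(fluxes, file.path(out, "fluxes.csv"))
    readr::write_csv(summaries, file.path(out, "summaries.csv"))
    if (nrow(comparisons) > 0) {
      readr::write_csv(comparisons, file.path(out, "comparisons.csv"))
    }
    if (nrow(tests) > 0) {
      readr::write_csv(tests, file.path(out, "tests.csv"))
    }
    if (!is.null(models)) {
      readr::write_csv(as_tibble(models), file.path(out, "models.csv"))
    }
    writeLines(log_lines, file.path(out, "run_log.txt"))
  }
  result
}

# one row per plot with per-element flux columns spread wide
flux_wide <- function(fluxes) {
  base <- fluxes |>
    filter(is.na(.data$error)) |>
    distinct(.data$plot_id, .data$site_id, .data$zone, .data$l_h, .data$h,
             .data$incidence, .data$fp)
  els <- fluxes |>
    filter(is.na(.data$error)) |>
    select("plot_id", "element", "h_c", "h_i", "re", "l_eh") |>
    tidyr::pivot_wider(
      names_from = "element",
      values_from = c("h_c", "h_i", "re", "l_eh"),
      names_sep = "_"
    )
  left_join(base, els, by = "plot_id")
}

#' @method print herbflux_run
#' @export
print.herbflux_run <- function(x, ...) {
  cat("<herbflux_run>\n")
  cat(sprintf("  %d flux rows (%d plots x %d elements)\n",
              nrow(x$fluxes), length(unique(x$fluxes$plot_id)),
              length(unique(x$fluxes$element))))
  cat("  tables: fluxes, summaries, comparisons, tests, models\n")
  invisible(x)
}

#' Rendered zone-summary and reference-comparison tables
#'
#' Formats the pipeline output as two report tables: zone means with
#' standard errors and Dunn letter groupings (letters are omitted when only
#' one zone is present), and the reference-comparison table of net N and P
#' fluxes against atmospheric deposition and bedrock weathering.
#'
#' @param run A `herbflux_run` from [run_all()].
#' @return A list with `zone_table` and `comparison_table` tibbles.
#' @export
report_tables <- function(run) {
  stopifnot(inherits(run, "herbflux_run"))
  multi_zone <- length(intersect(unique(run$summaries$zone), zone_levels)) > 1

  zone_table <- run$summaries |>
    filter(.data$zone != "global") |>
    mutate(mean_se = sprintf("%.3g ± %.2g", .data$mean, .data$se))
  if (multi_zone && nrow(run$letters) > 0) {
    zl <- run$letters |>
      tidyr::separate_rows("letters", sep = ";") |>
      tidyr::separate("letters", into = c("zone", "letter"), sep = "=")
    zone_table <- zone_table |>
      left_join(zl, by = c("variable", "zone")) |>
      mutate(mean_se = ifelse(is.na(.data$letter), .data$mean_se,
                              paste0(.data$mean_se, " ", .data$letter))) |>
      select(-"letter")
  }
  zone_table <- zone_table |>
    select("variable", "zone", "mean_se", "n") |>
    tidyr::pivot_wider(names_from = "zone", values_from = c("mean_se", "n"))

  comparison_table <- if (nrow(run$comparisons) > 0) {
    run$comparisons |>
      mutate(label = sprintf("%s vs %s", .data$flux, .data$reference)) |>
      select("zone", "label", "percent", "exceedance_pct") |>
      tidyr::pivot_wider(names_from = "label",
                         values_from = c("percent", "exceedance_pct"))
  } else {
    tibble()
  }

  list(zone_table = zone_table, comparison_table = comparison_table)
}
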