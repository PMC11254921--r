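#' Forest-network dataset bundle
#'
#' The package works on a bundle of six tables mirroring the field tables of
#' a litter-trap plot network:
#'
#' * `plots`: one row per plot — `plot_id`, `site_id`, `latitude` (signed
#'   degrees), `abs_latitude` (derived), `zone` (`tropical`/`temperate`/
#'   `boreal`, given metadata, never derived from latitude), `mat` (mean
#'   annual temperature, degrees C), `pet`, `map` (mm per year), `dryness`
#'   (PET/MAP, derived), `phenology` (`evergreen`/`deciduous`), `n_traps`,
#'   `trap_area` (m2).
#' * `soil`: per-plot soil panel — mass fractions `s_c`, `s_n`, `s_p`,
#'   `s_si` and stoichiometric ratios `s_cn`, `s_cp`.
#' * `traps`: litter-trap collections — `trap_id`, `plot_id`, `date_start`,
#'   `date_end`, `leaf_dry_mass` (g), `trap_area` (m2).
#' * `damage`: leaf-damage tallies — `plot_id`, `scan_date`, `n_undamaged`,
#'   `n_c1` ... `n_c6`.
#' * `chemistry`: per plot x element — `element` (`C`/`N`/`P`/`Si`),
#'   `f_green` and `c_litter` as mass fractions, `season`.
#' * `references`: labile-nutrient reference fluxes — `scope` (plot id or
#'   zone), `atm_n`, `atm_p`, `bedrock_p` (g m-2 y-1).
#'
#' Concentrations are stored internally as mass fractions in `[0, 1]`; all
#' CSV I/O uses percent, matching how element panels are printed in field
#' tables. Fluxes are always g m-2 y-1, areas m2, dates ISO-8601.
#'
#' @param plots,soil,traps,damage,chemistry,references The six tables.
#' @return An object of class `forest_bundle` (a named list of tibbles).
#' @export
forest_bundle <- function(plots, soil, traps, damage, chemistry, references) {
  bundle <- structure(
    list(
      plots = as_tibble(plots), soil = as_tibble(soil),
      traps = as_tibble(traps), damage = as_tibble(damage),
      chemistry = as_tibble(chemistry), references = as_tibble(references)
    ),
    class = "forest_bundle"
  )
  bundle$plots <- derive_plot_fields(bundle$plots)
  bundle
}

#' @method print forest_bundle
#' @export
print.forest_bundle <- function(x, ...) {
  cat("<forest_bundle>\n")
  cat(sprintf("  %d plots at %d sites; %d trap collections; %d damage scans\n",
              nrow(x$plots), length(unique(x$plots$site_id)),
              nrow(x$traps), nrow(x$damage)))
  cat(sprintf("  chemistry rows: %d; reference rows: %d\n",
              nrow(x$chemistry), nrow(x$references)))
  invisible(x)
}

zone_levels <- c("tropical", "temperate", "boreal")
phenology_levels <- c("evergreen", "deciduous")
element_levels <- c("C", "N", "P", "Si")

derive_plot_fields <- function(plots) {
  plots |>
    mutate(
      abs_latitude = abs(.data$latitude),
      dryness = .data$pet / .data$map
    )
}

#' Convert between percent and mass-fraction units
#'
#' Percent columns in CSV files are divided by 100 on read and multiplied by
#' 100 on write. `pct_to_fraction()` is involutive-safe only in one
#' direction; the bundle always holds fractions so normalization is applied
#' exactly once at the I/O boundary.
#'
#' @param x Numeric vector.
#' @return Numeric vector.
#' @keywords internal
pct_to_fraction <- function(x) x / 100

#' @rdname pct_to_fraction
#' @keywords internal
fraction_to_pct <- function(x) x * 100

bundle_csv_files <- c(
  plots = "plots.csv", soil = "soil.csv", traps = "traps.csv",
  damage = "damage.csv", chemistry = "chemistry.csv",
  references = "references.csv"
)

required_columns <- list(
  plots = c("plot_id", "site_id", "latitude", "zone", "mat_c", "pet_mm",
            "map_mm", "phenology", "n_traps", "trap_area_m2"),
  soil = c("plot_id", "s_c_pct", "s_n_pct", "s_p_pct", "s_si_pct"),
  traps = c("trap_id", "plot_id", "date_start", "date_end",
            "leaf_dry_mass_g", "trap_area_m2"),
  damage = c("plot_id", "scan_date", "n_undamaged", paste0("n_c", 1:6)),
  chemistry = c("plot_id", "element", "tissue", "concentration_pct", "season"),
  references = c("scope", "atm_n", "atm_p", "bedrock_p")
)

read_checked_csv <- function(path, table) {
  if (!file.exists(path)) {
    abort(sprintf("File not found for table '%s': %s", table, path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(required_columns[[table]], names(df))
  if (length(missing) > 0) {
    abort(sprintf("Table '%s' (%s) is missing required column(s): %s",
                  table, path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a forest-network dataset from CSV files
#'
#' Reads the six-table CSV bundle (see [forest_bundle()] for the schema),
#' normalizes percent columns to mass fractions, derives `abs_latitude` and
#' `dryness`, and checks categorical labels.
#'
#' @param dir Directory containing `plots.csv`, `soil.csv`, `traps.csv`,
#'   `damage.csv`, `chemistry.csv` and `references.csv`. Alternatively pass
#'   `paths`, a named character vector overriding individual file locations.
#' @param paths Optional named character vector (names among `plots`,
#'   `soil`, `traps`, `damage`, `chemistry`, `references`).
#' @return A [forest_bundle()].
#' @export
read_dataset <- function(dir = ".", paths = NULL) {
  files <- file.path(dir, bundle_csv_files)
  names(files) <- names(bundle_csv_files)
  if (!is.null(paths)) files[names(paths)] <- paths

  plots_raw <- read_checked_csv(files["plots"], "plots")
  bad_zone <- setdiff(unique(plots_raw$zone), zone_levels)
  if (length(bad_zone) > 0) {
    abort(paste0("Unknown zone label(s): ", paste(bad_zone, collapse = ", ")))
  }
  bad_phen <- setdiff(unique(plots_raw$phenology), phenology_levels)
  if (length(bad_phen) > 0) {
    abort(paste0("Unknown phenology label(s): ", paste(bad_phen, collapse = ", ")))
  }
  plots <- plots_raw |>
    transmute(
      plot_id = as.character(.data$plot_id),
      site_id = as.character(.data$site_id),
      latitude = .data$latitude,
      zone = .data$zone,
      mat = .data$mat_c,
      pet = .data$pet_mm,
      map = .data$map_mm,
      phenology = .data$phenology,
      n_traps = as.integer(.data$n_traps),
      trap_area = .data$trap_area_m2
    )

  soil <- read_checked_csv(files["soil"], "soil") |>
    transmute(
      plot_id = as.character(.data$plot_id),
      s_c = pct_to_fraction(.data$s_c_pct),
      s_n = pct_to_fraction(.data$s_n_pct),
      s_p = pct_to_fraction(.data$s_p_pct),
      s_si = pct_to_fraction(.data$s_si_pct)
    ) |>
    mutate(
      s_cn = ifelse(.data$s_n > 0, .data$s_c / .data$s_n, NA_real_),
      s_cp = ifelse(.data$s_p > 0, .data$s_c / .data$s_p, NA_real_)
    )

  traps <- read_checked_csv(files["traps"], "traps") |>
    transmute(
      trap_id = as.character(.data$trap_id),
      plot_id = as.character(.data$plot_id),
      date_start = as.Date(.data$date_start),
      date_end = as.Date(.data$date_end),
      leaf_dry_mass = .data$leaf_dry_mass_g,
      trap_area = .data$trap_area_m2
    )

  damage <- read_checked_csv(files["damage"], "damage") |>
    mutate(
      plot_id = as.character(.data$plot_id),
      scan_date = as.Date(.data$scan_date),
      across(dplyr::all_of(c("n_undamaged", paste0("n_c", 1:6))), as.integer)
    )
  zero_rows <- damage$n_undamaged + rowSums(damage[paste0("n_c", 1:6)]) == 0
  if (any(zero_rows)) {
    offenders <- damage[zero_rows, c("plot_id", "scan_date")]
    abort(paste0(
      "Damage tallies with zero scored leaves for: ",
      paste(sprintf("%s@%s", offenders$plot_id, offenders$scan_date),
            collapse = "; ")
    ))
  }

  chem_raw <- read_checked_csv(files["chemistry"], "chemistry")
  bad_el <- setdiff(unique(chem_raw$element), element_levels)
  if (length(bad_el) > 0) {
    abort(paste0("Unknown element label(s): ", paste(bad_el, collapse = ", ")))
  }
  bad_tissue <- setdiff(unique(chem_raw$tissue), c("green", "litter"))
  if (length(bad_tissue) > 0) {
    abort(paste0("Unknown tissue label(s): ", paste(bad_tissue, collapse = ", ")))
  }
  chemistry <- chem_raw |>
    mutate(
      plot_id = as.character(.data$plot_id),
      concentration = pct_to_fraction(.data$concentration_pct)
    ) |>
    select("plot_id", "element", "tissue", "concentration", "season") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "concentration") |>
    rename(f_green = "green", c_litter = "litter") |>
    select("plot_id", "element", "f_green", "c_litter", "season")

  references <- read_checked_csv(files["references"], "references") |>
    mutate(scope = as.character(.data$scope))

  forest_bundle(plots, soil, traps, damage, chemistry, references)
}

#' Write a forest-network dataset to CSV files
#'
#' Inverse of [read_dataset()]: mass fractions are written back as percent,
#' derived fields (`abs_latitude`, `dryness`) are dropped, dates are
#' ISO-8601. A write-then-read round trip reproduces the bundle.
#'
#' @param bundle A [forest_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "forest_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  bundle$plots |>
    transmute(
      plot_id = .data$plot_id, site_id = .data$site_id,
      latitude = .data$latitude, zone = .data$zone,
      mat_c = .data$mat, pet_mm = .data$pet, map_mm = .data$map,
      phenology = .data$phenology, n_traps = .data$n_traps,
      trap_area_m2 = .data$trap_area
    ) |>
    readr::write_csv(file.path(dir, "plots.csv"))

  bundle$soil |>
    transmute(
      plot_id = .data$plot_id,
      s_c_pct = fraction_to_pct(.data$s_c),
      s_n_pct = fraction_to_pct(.data$s_n),
      s_p_pct = fraction_to_pct(.data$s_p),
      s_si_pct = fraction_to_pct(.data$s_si)
    ) |>
    readr::write_csv(file.path(dir, "soil.csv"))

  bundle$traps |>
    transmute(
      trap_id = .data$trap_id, plot_id = .data$plot_id,
      date_start = .data$date_start, date_end = .data$date_end,
      leaf_dry_mass_g = .data$leaf_dry_mass, trap_area_m2 = .data$trap_area
    ) |>
    readr::write_csv(file.path(dir, "traps.csv"))

  readr::write_csv(bundle$damage, file.path(dir, "damage.csv"))

  bundle$chemistry |>
    tidyr::pivot_longer(c("f_green", "c_litter"), names_to = "tissue",
                        values_to = "concentration") |>
    mutate(
      tissue = ifelse(.data$tissue == "f_green", "green", "litter"),
      concentration_pct = fraction_to_pct(.data$concentration)
    ) |>
    select("plot_id", "element", "tissue", "concentration_pct", "season") |>
    readr::write_csv(file.path(dir, "chemistry.csv"))

  readr::write_csv(bundle$references, file.path(dir, "references.csv"))
  invisible(dir)
}

add_finding <- function(findings, table, id, field, message) {
  dplyr::bind_rows(findings, tibble(
    table = table, record = as.character(id), field = field, message = message
  ))
}

#' Validate a forest-network dataset
#'
#' Checks record-level invariants: positive precipitation, `dryness` equal
#' to PET/MAP, `abs_latitude` equal to `|latitude|`, soil fractions in
#' `[0, 1]`, trap interval ordering and plausibility (1--120 days, with a
#' warning flag outside 14--31), non-negative masses, trap areas in
#' `(0, 1]` m2, usable damage tallies, and chemistry fractions in `(0, 1)`.
#'
#' @param bundle A [forest_bundle()].
#' @return A tibble of findings (`table`, `record`, `field`, `message`) with
#'   attribute `ok` (`TRUE` iff no findings). Warnings (non-fatal
#'   plausibility notes) carry `"warning:"` prefixes and do not fail
#'   validation.
#' @export
validate_dataset <- function(bundle) {
  stopifnot(inherits(bundle, "forest_bundle"))
  findings <- tibble(
    table = character(), record = character(),
    field = character(), message = character()
  )

  p <- bundle$plots
  for (i in seq_len(nrow(p))) {
    if (!is.finite(p$map[i]) || p$map[i] <= 0) {
      findings <- add_finding(findings, "plots", p$plot_id[i], "map",
                              "mean annual precipitation must be > 0")
    } else if (abs(p$dryness[i] - p$pet[i] / p$map[i]) >
               1e-9 * max(1, abs(p$dryness[i]))) {
      findings <- add_finding(
        findings, "plots", p$plot_id[i], "dryness",
        sprintf("dryness %.6g != pet/map = %.6g", p$dryness[i],
                p$pet[i] / p$map[i])
      )
    }
    if (abs(p$abs_latitude[i] - abs(p$latitude[i])) > 1e-12) {
      findings <- add_finding(findings, "plots", p$plot_id[i], "abs_latitude",
                              "abs_latitude != |latitude|")
    }
    if (!p$zone[i] %in% zone_levels) {
      findings <- add_finding(findings, "plots", p$plot_id[i], "zone",
                              paste0("unknown zone: ", p$zone[i]))
    }
    if (!p$phenology[i] %in% phenology_levels) {
      findings <- add_finding(findings, "plots", p$plot_id[i], "phenology",
                              paste0("unknown phenology: ", p$phenology[i]))
    }
  }

  s <- bundle$soil
  for (col in c("s_c", "s_n", "s_p", "s_si")) {
    bad <- which(!is.na(s[[col]]) & (s[[col]] < 0 | s[[col]] > 1))
    for (i in bad) {
      findings <- add_finding(findings, "soil", s$plot_id[i], col,
                              "soil mass fraction outside [0, 1]")
    }
  }

  tr <- bundle$traps
  interval <- as.numeric(tr$date_end - tr$date_start)
  for (i in seq_len(nrow(tr))) {
    if (interval[i] <= 0) {
      findings <- add_finding(findings, "traps", tr$trap_id[i], "date_end",
                              "date_end must be after date_start")
    } else if (interval[i] > 120) {
      findings <- add_finding(findings, "traps", tr$trap_id[i], "interval",
                              sprintf("interval of %d days exceeds 120", interval[i]))
    } else if (interval[i] < 14 || interval[i] > 31) {
      findings <- add_finding(
        findings, "traps", tr$trap_id[i], "interval",
        sprintf("warning: interval of %d days outside the usual 14-31",
                interval[i])
      )
    }
    if (tr$leaf_dry_mass[i] < 0) {
      findings <- add_finding(findings, "traps", tr$trap_id[i],
                              "leaf_dry_mass", "mass must be >= 0")
    }
    if (tr$trap_area[i] <= 0 || tr$trap_area[i] > 1) {
      findings <- add_finding(findings, "traps", tr$trap_id[i], "trap_area",
                              "trap area must be in (0, 1] m2")
    }
  }

  d <- bundle$damage
  counts <- d$n_undamaged + rowSums(d[paste0("n_c", 1:6)])
  for (i in which(counts == 0)) {
    findings <- add_finding(
      findings, "damage", sprintf("%s@%s", d$plot_id[i], d$scan_date[i]),
      "counts", "tally has zero scored leaves"
    )
  }
  neg <- which(apply(d[c("n_undamaged", paste0("n_c", 1:6))] < 0, 1, any))
  for (i in neg) {
    findings <- add_finding(
      findings, "damage", sprintf("%s@%s", d$plot_id[i], d$scan_date[i]),
      "counts", "negative count"
    )
  }

  ch <- bundle$chemistry
  for (col in c("f_green", "c_litter")) {
    bad <- which(!is.na(ch[[col]]) & (ch[[col]] <= 0 | ch[[col]] >= 1))
    for (i in bad) {
      findings <- add_finding(
        findings, "chemistry",
        sprintf("%s/%s", ch$plot_id[i], ch$element[i]), col,
        "concentration fraction outside (0, 1)"
      )
    }
  }

  rf <- bundle$references
  for (col in c("atm_n", "atm_p", "bedrock_p")) {
    bad <- which(!is.na(rf[[col]]) & rf[[col]] < 0)
    for (i in bad) {
      findings <- add_finding(findings, "references", rf$scope[i], col,
                              "reference flux must be >= 0")
    }
  }

  fatal <- findings[!startsWith(findings$message, "warning:"), ]
  attr(findings, "ok") <- nrow(fatal) == 0
  findings
}
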