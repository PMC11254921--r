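test_that("write-then-read round-trips a dataset bundle", {
  b <- generate_network(synthetic_config(n_sites = 6), seed = 7)
  dir <- withr::local_tempdir()
  write_dataset(b, dir)
  b2 <- read_dataset(dir)
  for (tbl in c("plots", "soil", "traps", "damage", "chemistry",
                "references")) {
    a <- dplyr::arrange_all(as.data.frame(b[[tbl]]))
    c2 <- dplyr::arrange_all(as.data.frame(b2[[tbl]]))
    expect_tables_equal(a, c2, tol = 1e-12)
  }
  # normalization is applied exactly once: a second write-read cycle
  # reproduces the first (no repeated percent/fraction scaling)
  dir2 <- withr::local_tempdir()
  write_dataset(b2, dir2)
  b3 <- read_dataset(dir2)
  for (tbl in names(b2)) {
    expect_tables_equal(as.data.frame(b2[[tbl]]), as.data.frame(b3[[tbl]]),
                        tol = 1e-12)
  }
})

test_that("percent columns are stored as fractions", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_dataset(b, dir)
  raw <- readr::read_csv(file.path(dir, "chemistry.csv"),
                         show_col_types = FALSE)
  n_green <- raw[raw$plot_id == "p1" & raw$element == "N" &
                   raw$tissue == "green", ]
  expect_equal(n_green$concentration_pct, 2) # percent on disk
  b2 <- read_dataset(dir)
  expect_equal(
    b2$chemistry$f_green[b2$chemistry$plot_id == "p1" &
                           b2$chemistry$element == "N"],
    0.02 # fraction in memory
  )
})

test_that("schema and value errors name the offending column or label", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_dataset(b, dir)

  plots <- readr::read_csv(file.path(dir, "plots.csv"), show_col_types = FALSE)
  readr::write_csv(plots[setdiff(names(plots), "mat_c")],
                   file.path(dir, "plots.csv"))
  expect_error(read_dataset(dir), "mat_c")

  readr::write_csv(dplyr::mutate(plots, zone = "subtropical"),
                   file.path(dir, "plots.csv"))
  expect_error(read_dataset(dir), "subtropical")
  readr::write_csv(plots, file.path(dir, "plots.csv"))

  damage <- readr::read_csv(file.path(dir, "damage.csv"),
                            show_col_types = FALSE)
  zeroed <- damage
  zeroed[1, c("n_undamaged", paste0("n_c", 1:6))] <- 0
  readr::write_csv(zeroed, file.path(dir, "damage.csv"))
  expect_error(read_dataset(dir), zeroed$plot_id[1])
})

test_that("validation reports per-record invariant violations", {
  b <- generate_network(synthetic_config(n_sites = 6), seed = 3)
  report <- validate_dataset(b)
  expect_true(attr(report, "ok"))

  bad <- b
  bad$traps$date_end[1] <- bad$traps$date_start[1] - 1
  report <- validate_dataset(bad)
  expect_false(attr(report, "ok"))
  expect_true(any(report$record == bad$traps$trap_id[1] &
                    report$field == "date_end"))

  bad2 <- b
  bad2$plots$dryness[2] <- bad2$plots$dryness[2] * 1.5
  report2 <- validate_dataset(bad2)
  expect_false(attr(report2, "ok"))
  hit <- report2[report2$field == "dryness", ]
  expect_equal(hit$record, bad2$plots$plot_id[2])
  # the finding carries the recomputed pet/map value
  expect_match(hit$message, sprintf(
    "%.6g", bad2$plots$pet[2] / bad2$plots$map[2]
  ), fixed = TRUE)

  bad3 <- b
  bad3$chemistry$f_green[1] <- 1.2
  expect_false(attr(validate_dataset(bad3), "ok"))
})
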