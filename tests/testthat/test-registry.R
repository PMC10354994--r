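# candidate_registry: validation, I/O round-trips, activity rule

test_that("registry validates enums, ids, names and year bounds", {
  expect_s3_class(registry(example_candidates(5)), "tpp_registry")

  df <- example_candidates(3)
  df$phase[2] <- "phaseX"
  err <- expect_error(registry(df), class = "tpp_value_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "phaseX")

  df <- example_candidates(3)
  df$id[3] <- df$id[1]
  expect_error(registry(df), class = "tpp_integrity_error")

  df <- example_candidates(2)
  df$name[1] <- ""
  expect_error(registry(df), class = "tpp_schema_error")

  df <- example_candidates(2)
  df$last_update_year[1] <- 2030L
  expect_error(registry(df), class = "tpp_value_error")
  expect_error(registry(example_candidates(2)[, -3]),
               class = "tpp_schema_error")
})

test_that("registry_problems reports exactly the violating rows", {
  # property: perturb k known rows of a valid table; the report names those
  # rows and no others
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    df <- example_candidates(n)
    bad_rows <- sort(sample(n, sample(1:3, 1)))
    for (i in bad_rows) df$indication[i] <- paste0("bogus", i)
    problems <- registry_problems(df)
    expect_setequal(problems$row, bad_rows)
  }
})

test_that("load/write round-trips CSV and JSON field-for-field", {
  df <- example_candidates(6)
  df$name[2] <- 'tricky, "quoted" name'   # forces CSV quoting
  df$route[3] <- NA
  df$marketed_for_indication[4] <- TRUE
  reg <- registry(df, snapshot_year = 2021L)
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_registry(reg, path, format = fmt)
    back <- load_registry(path, format = fmt)
    expect_equal(back$candidates, reg$candidates)
    expect_identical(back$snapshot_year, reg$snapshot_year)
  }
})

test_that("empty registries round-trip and summarize to zeros", {
  reg <- registry(example_candidates(0))
  expect_identical(nrow(reg$candidates), 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  expect_identical(nrow(load_registry(path)$candidates), 0L)
  s <- summarize_registry(reg)
  expect_identical(s$total, 0L)
  expect_identical(nrow(s$by_phase), 0L)
})

test_that("unknown columns are retained as opaque annotations", {
  df <- example_candidates(3)
  df$custom_note <- c("a", "b", "c")
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(registry(df), path)
  expect_identical(load_registry(path)$candidates$custom_note, df$custom_note)
})

test_that("is_active matches the year/cutoff decision table", {
  # oracle: enumerate all year/cutoff combinations in 2015..2021, plus the
  # absent-year case, against the rule year >= cutoff
  for (cutoff in 2015:2021) {
    for (year in 2015:2021) {
      expect_identical(is_active(year, cutoff), year >= cutoff)
    }
    expect_false(is_active(NA_integer_, cutoff))
  }
  expect_true(is_active(2020, 2018))
  expect_false(is_active(2017, 2018))
  expect_error(is_active(2020, 0), class = "tpp_usage_error")
})

test_that("is_active partitions any registry", {
  set.seed(11)
  for (rep in 1:5) {
    cfg <- generator_config(n_candidates = 40, seed = rep)
    reg <- generate_registry(cfg)
    act <- is_active(reg)
    expect_identical(sum(act) + sum(!act), nrow(reg$candidates))
  }
})
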