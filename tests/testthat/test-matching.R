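# tpp_matching: sheet validation, adjudication, agreement

test_that("validate_sheet accepts exactly the scale-admissible sheets", {
  expect_s3_class(uniform_sheet("met_preferred"), "tpp_rating_sheet")
  expect_s3_class(sheet_with("setting", "single_setting"), "tpp_rating_sheet")
  # exhaustive admissibility sweep: every (parameter, level) pair
  for (p in tpp_parameters()) {
    for (lv in rating_levels()) {
      build <- function() sheet_with(p, lv, base_level = "unknown")
      if (lv %in% admissible_levels(p)) {
        expect_s3_class(build(), "tpp_rating_sheet")
      } else {
        expect_error(build(), class = "tpp_value_error")
      }
    }
  }
  # missing parameter
  lv <- stats::setNames(rep("not_met", 8), tpp_parameters()[-2])
  expect_error(rating_sheet("c", "r", lv), class = "tpp_schema_error")
})

test_that("level aliases normalize to canonical tokens", {
  sh <- rating_sheet("c", "r", stats::setNames(
    c("both_settings", rep("met_minimum", 6), "met", "not_met"),
    tpp_parameters()))
  expect_identical(unname(sh$levels[["setting"]]), "met_preferred")
  expect_identical(unname(sh$levels[["stability"]]), "met_preferred")
})

test_that("adjudicate merges per the three-way truth table", {
  a <- uniform_sheet("unknown", rater_id = "rater_a")
  # identical sheets, no third
  adj <- adjudicate(a, uniform_sheet("unknown", rater_id = "rater_b"))
  expect_identical(adj$merged$levels, a$levels)
  expect_identical(nrow(adj$disagreements), 0L)
  expect_false(adj$unresolved)

  # one disagreement resolved by third
  b <- sheet_with("efficacy", "partial_minimum", base_level = "unknown",
                  rater_id = "rater_b")
  adj <- adjudicate(a, b, third = c(efficacy = "met_minimum"))
  expect_identical(unname(adj$merged$levels[["efficacy"]]), "met_minimum")
  expect_identical(adj$resolved_by_third, "efficacy")
  expect_false(adj$unresolved)

  # two disagreements, third covers one -> unresolved, unscorable
  b2 <- b; b2$levels[["safety"]] <- "not_met"
  adj2 <- adjudicate(a, b2, third = c(efficacy = "met_minimum"))
  expect_true(adj2$unresolved)
  expect_identical(adj2$unresolved_parameters, "safety")
  expect_error(score_sheet(adj2$merged), class = "tpp_usage_error")

  # errors
  expect_error(adjudicate(a, uniform_sheet("unknown", candidate_id = "other")),
               class = "tpp_usage_error")
  expect_error(adjudicate(a, b, third = c(stability = "met_minimum")),
               class = "tpp_value_error")
})

test_that("adjudicate is symmetric when the third map covers disagreements", {
  set.seed(7)
  for (rep in 1:20) {
    a <- random_sheet(rater_id = "rater_a")
    b <- random_sheet(rater_id = "rater_b")
    disagree <- tpp_parameters()[a$levels != b$levels]
    third <- vapply(disagree, function(p) {
      adm <- admissible_levels(p); adm[[sample.int(length(adm), 1L)]]
    }, character(1))
    m1 <- adjudicate(a, b, third = third)$merged$levels
    m2 <- adjudicate(b, a, third = third)$merged$levels
    expect_identical(m1, m2)
  }
})

test_that("agreement_rate counts matching parameters out of nine", {
  a <- uniform_sheet("unknown", rater_id = "ra")
  expect_identical(agreement_rate(a, a), 1)
  flipped <- rating_sheet("c1", "rb", vapply(tpp_parameters(), function(p) {
    setdiff(admissible_levels(p), "unknown")[[1L]]
  }, character(1)))
  expect_identical(agreement_rate(a, flipped), 0)
  b <- a
  for (p in c("efficacy", "safety", "adherence")) b$levels[[p]] <- "not_met"
  b <- rating_sheet("c1", "rb", b$levels)
  expect_equal(agreement_rate(a, b), 6 / 9, tolerance = 1e-9)
  # identity property on random sheets
  set.seed(21)
  for (rep in 1:20) {
    s <- random_sheet()
    expect_identical(agreement_rate(s, s), 1)
  }
  expect_error(agreement_rate(a, uniform_sheet("unknown", candidate_id = "zz")),
               class = "tpp_usage_error")
})

test_that("sheet collections round-trip through CSV and JSON", {
  set.seed(13)
  sheets <- lapply(1:5, function(i) random_sheet(candidate_id = paste0("c", i)))
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_sheets(sheets, path, format = fmt)
    back <- load_sheets(path, format = fmt)
    expect_identical(lapply(back, `[[`, "levels"),
                     lapply(sheets, `[[`, "levels"))
    expect_identical(vapply(back, `[[`, character(1), "candidate_id"),
                     vapply(sheets, `[[`, character(1), "candidate_id"))
  }
})
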