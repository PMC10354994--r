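# scoring_rank: scheme, weighted scores, tiers

test_that("default scheme has the documented shape and maximum 33", {
  sch <- default_scheme()
  # hand-sum oracle: 3 * (2 + 2 + 7*1)
  expect_identical(max_achievable(sch), 3 * (2 + 2 + 7 * 1))
  expect_true(sch$weights[["efficacy"]] > sch$weights[["adherence"]])
  expect_true(sch$weights[["safety"]] > sch$weights[["administration"]])
  expect_identical(unname(sch$level_codes[rating_levels()]), c(3, 2, 1, 0, 0))
  expect_identical(sch$unknown_policy, "score_zero")
})

test_that("scheme construction rejects invariant violations", {
  sch <- default_scheme()
  expect_error(scoring_scheme(c(sch$level_codes[-5], unknown = 2),
                              sch$weights, sch$thresholds),
               class = "tpp_config_error")
  w <- sch$weights; w[["efficacy"]] <- 1
  expect_error(scoring_scheme(sch$level_codes, w, sch$thresholds),
               class = "tpp_config_error")
  th <- sch$thresholds; th$phase2$medium_cut <- 0.9
  expect_error(scoring_scheme(sch$level_codes, sch$weights, th),
               class = "tpp_config_error")
})

test_that("score_sheet computes the weighted sum (brute-force perturbation oracle)", {
  sch <- default_scheme()
  top <- score_sheet(uniform_sheet("met_preferred"), sch)
  expect_identical(top$weighted_score, 33)
  expect_identical(top$max_achievable, 33)
  zero <- score_sheet(floor_sheet(), sch)
  expect_identical(zero$weighted_score, 0)

  # single-parameter perturbations from all-preferred: independent oracle
  # computes 33 - w_p * (3 - code(level)) directly
  for (p in tpp_parameters()) {
    for (lv in admissible_levels(p)) {
      got <- score_sheet(sheet_with(p, lv), sch)$weighted_score
      expected <- 33 - sch$weights[[p]] * (3 - sch$level_codes[[lv]])
      expect_identical(got, expected)
    }
  }
  expect_identical(score_sheet(sheet_with("efficacy", "met_minimum"),
                               sch)$weighted_score, 31)
})

test_that("unknown policies score grey cells as documented", {
  sch0 <- default_scheme()
  renorm <- scoring_scheme(sch0$level_codes, sch0$weights, sch0$thresholds,
                           unknown_policy = "exclude_and_renormalize")
  sheet <- sheet_with("adherence", "unknown")
  expect_identical(score_sheet(sheet, sch0)$weighted_score, 33 - 3)
  expect_identical(score_sheet(sheet, sch0)$max_achievable, 33)
  sc <- score_sheet(sheet, renorm)
  expect_identical(sc$weighted_score, 30)
  expect_identical(sc$max_achievable, 30)
  expect_identical(sc$score_fraction, 1)
  expect_error(score_sheet(uniform_sheet("unknown"), renorm),
               class = "tpp_degenerate_error")
})

test_that("tier boundaries belong to the upper tier at every phase", {
  sch <- default_scheme()
  for (phase in tpp_rankable_phases()) {
    expect_identical(rank_tier(c(0.39, 0.40, 0.69, 0.70), phase, sch),
                     c("low", "medium", "medium", "high"))
    expect_identical(rank_tier(1.0, phase, sch), "high")
    expect_identical(rank_tier(0, phase, sch), "low")
  }
  for (bad in c("phase4", "marketed", "preclinical")) {
    expect_error(rank_tier(0.5, bad), class = "tpp_usage_error")
  }
})

test_that("score and tier are monotone under single-parameter improvement", {
  # smaller-n development property; the acceptance suite runs 10^4 sheets
  sch <- default_scheme()
  ladders <- list(
    ordinal5 = c("unknown", "not_met", "partial_minimum", "met_minimum",
                 "met_preferred"),
    setting3 = c("unknown", "partial_minimum", "met_preferred"),
    binary_unknown = c("unknown", "not_met", "met_preferred"))
  tier_ord <- c(low = 1L, medium = 2L, high = 3L)
  set.seed(4242)
  for (rep in 1:200) {
    s <- random_sheet(rater_id = "consensus")
    p <- sample(tpp_parameters(), 1L)
    ladder <- ladders[[parameter_scales()[[p]]]]
    pos <- match(s$levels[[p]], ladder)
    if (pos == length(ladder)) next
    improved <- rating_sheet(s$candidate_id, s$rater_id,
                             replace(s$levels, p, ladder[[pos + 1L]]))
    s0 <- score_sheet(s, sch); s1 <- score_sheet(improved, sch)
    expect_gte(s1$weighted_score, s0$weighted_score)
    expect_gte(tier_ord[[rank_tier(s1$score_fraction, "phase2", sch)]],
               tier_ord[[rank_tier(s0$score_fraction, "phase2", sch)]])
  }
})

test_that("scheme config round-trips and scores identically", {
  sch <- scoring_scheme(
    level_codes = c(met_preferred = 4, met_minimum = 2, partial_minimum = 1,
                    not_met = 0, unknown = 0),
    weights = stats::setNames(c(1, 3, 1, 1, 3, 1, 1, 1, 1), tpp_parameters()),
    thresholds = list(phase1 = list(high_cut = 0.8, medium_cut = 0.5),
                      phase2 = list(high_cut = 0.7, medium_cut = 0.4),
                      phase3 = list(high_cut = 0.6, medium_cut = 0.3)),
    unknown_policy = "exclude_and_renormalize")
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme(sch, path)
  back <- read_scheme(path)
  set.seed(5)
  for (rep in 1:20) {
    s <- random_sheet(rater_id = "consensus")
    if (all(s$levels == "unknown")) next
    expect_identical(score_sheet(s, back), score_sheet(s, sch))
  }
})

test_that("rank_registry ties screening, sheets and tiers together", {
  df <- example_candidates(3)
  df$phase <- c("phase2", "phase2", "phase3")
  df$inferior_to_current[3] <- TRUE   # screened out, needs no sheet
  reg <- registry(df)
  sheets <- list(uniform_sheet("met_preferred", candidate_id = df$id[1]),
                 floor_sheet(candidate_id = df$id[2]))
  res <- rank_registry(reg, sheets)
  expect_identical(unname(res$tally), c(1L, 0L, 1L))
  expect_identical(res$results$tier[res$results$candidate_id == df$id[1]], "high")
  expect_length(res$missing, 0L)

  # missing sheet -> warning + excluded from tally
  expect_warning(res2 <- rank_registry(reg, sheets[1]), "no adjudicated sheet")
  expect_identical(res2$missing, df$id[2])
  expect_identical(sum(res2$tally), 1L)

  # empty input
  empty <- rank_registry(registry(example_candidates(0)), list())
  expect_identical(nrow(empty$results), 0L)
  expect_identical(sum(empty$tally), 0L)
})

test_that("weight dominance: efficacy drop outweighs any unit-weight drop", {
  sch <- default_scheme()
  base <- score_sheet(uniform_sheet("met_preferred"), sch)$weighted_score
  eff_drop <- base - score_sheet(sheet_with("efficacy", "not_met"),
                                 sch)$weighted_score
  for (p in setdiff(tpp_parameters(), c("efficacy", "safety"))) {
    worst <- if ("not_met" %in% admissible_levels(p)) "not_met" else "unknown"
    drop <- base - score_sheet(sheet_with(p, worst), sch)$weighted_score
    expect_gt(eff_drop, drop)
  }
})
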