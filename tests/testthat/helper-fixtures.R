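# Shared in-code fixtures for the suite. Everything is generated here; no
# binary data.

uniform_sheet <- function(level, candidate_id = "c1", rater_id = "consensus") {
  rating_sheet(candidate_id, rater_id,
               stats::setNames(rep(level, 9), tpp_parameters()))
}

# the lowest-coded admissible level per parameter: not_met where the scale
# admits it, unknown on the setting scale (scores 0 under the defaults)
floor_sheet <- function(candidate_id = "c1", rater_id = "consensus") {
  lv <- vapply(tpp_parameters(), function(p) {
    if ("not_met" %in% admissible_levels(p)) "not_met" else "unknown"
  }, character(1))
  rating_sheet(candidate_id, rater_id, lv)
}

# a sheet with one parameter overridden
sheet_with <- function(parameter, level, base_level = "met_preferred",
                       candidate_id = "c1", rater_id = "consensus") {
  lv <- stats::setNames(rep(base_level, 9), tpp_parameters())
  lv[[parameter]] <- level
  rating_sheet(candidate_id, rater_id, lv)
}

# random admissible sheet under the session RNG (callers set the seed)
random_sheet <- function(candidate_id = "c1", rater_id = "rater_a") {
  lv <- vapply(tpp_parameters(), function(p) {
    adm <- admissible_levels(p)
    adm[[sample.int(length(adm), 1L)]]
  }, character(1))
  rating_sheet(candidate_id, rater_id, lv)
}

# small registry with chosen eligibility flags; flags is a list keyed by row
flagged_registry <- function(n, flags = list()) {
  df <- example_candidates(n)
  df$phase <- "phase2"
  for (row in names(flags)) {
    for (f in flags[[row]]) df[[f]][as.integer(row)] <- TRUE
  }
  registry(df)
}
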