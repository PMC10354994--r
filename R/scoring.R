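# Weighted scoring of adjudicated rating sheets and phase-specific tiers.

#' Construct or retrieve a scoring scheme
#'
#' A scheme holds (i) the level-to-code map, (ii) per-parameter weights,
#' (iii) per-phase tier thresholds expressed as fractions of the maximum
#' achievable weighted score, and (iv) the policy for `unknown` ratings.
#' The published supplementary constants are not reproduced in the source
#' article's main text, so `default_scheme()` returns this package's
#' documented convention: codes 3/2/1/0 (unknown 0), weight 2 on efficacy
#' and safety and 1 elsewhere, and cuts high = 0.70, medium = 0.40 at every
#' clinical phase. All of it is configurable and serializable.
#'
#' @param level_codes Named non-negative numeric over [rating_levels()],
#'   non-increasing from `met_preferred` to `not_met`, with
#'   `unknown <= partial_minimum`.
#' @param weights Named positive numeric over [tpp_parameters()]; efficacy
#'   and safety must strictly dominate every other weight.
#' @param thresholds Named list over phases `phase1`, `phase2`, `phase3`,
#'   each `list(high_cut=, medium_cut=)` with `0 < medium_cut < high_cut <= 1`.
#' @param unknown_policy `"score_zero"` (default; grey cells contribute the
#'   `unknown` code) or `"exclude_and_renormalize"` (grey cells drop out of
#'   both the score and the achievable maximum).
#' @return Object of class `tpp_scoring_scheme`.
#' @examples
#' sch <- default_scheme()
#' max_achievable(sch)   # 33 under the defaults
#' @export
scoring_scheme <- function(level_codes, weights, thresholds,
                           unknown_policy = c("score_zero",
                                              "exclude_and_renormalize")) {
  unknown_policy <- match.arg(unknown_policy)
  lv <- rating_levels()
  if (!all(lv %in% names(level_codes))) {
    tpp_error("tpp_config_error", "level_codes must cover all five rating levels")
  }
  level_codes <- vapply(level_codes[lv], as.numeric, numeric(1))
  if (any(level_codes < 0)) {
    tpp_error("tpp_config_error", "level codes must be non-negative")
  }
  if (!(level_codes[["met_preferred"]] >= level_codes[["met_minimum"]] &&
        level_codes[["met_minimum"]] >= level_codes[["partial_minimum"]] &&
        level_codes[["partial_minimum"]] >= level_codes[["not_met"]])) {
    tpp_error("tpp_config_error",
              "level codes must be non-increasing from met_preferred to not_met")
  }
  if (level_codes[["unknown"]] > level_codes[["partial_minimum"]]) {
    tpp_error("tpp_config_error",
              "unknown must not code higher than partial_minimum")
  }
  params <- tpp_parameters()
  if (!all(params %in% names(weights))) {
    tpp_error("tpp_config_error", "weights must cover all nine parameters")
  }
  weights <- vapply(weights[params], as.numeric, numeric(1))
  if (any(weights <= 0)) tpp_error("tpp_config_error", "weights must be positive")
  others <- setdiff(params, c("efficacy", "safety"))
  if (!(all(weights[["efficacy"]] > weights[others]) &&
        all(weights[["safety"]] > weights[others]))) {
    tpp_error("tpp_config_error",
              "efficacy and safety must carry strictly greater weight than other parameters")
  }
  ph <- tpp_rankable_phases()
  if (!all(ph %in% names(thresholds))) {
    tpp_error("tpp_config_error", "thresholds must cover phase1, phase2, phase3")
  }
  thresholds <- lapply(thresholds[ph], function(t) {
    t <- list(high_cut = as.numeric(t$high_cut), medium_cut = as.numeric(t$medium_cut))
    if (!(t$medium_cut > 0 && t$medium_cut < t$high_cut && t$high_cut <= 1)) {
      tpp_error("tpp_config_error", "need 0 < medium_cut < high_cut <= 1")
    }
    t
  })
  structure(list(level_codes = level_codes, weights = weights,
                 thresholds = thresholds, unknown_policy = unknown_policy),
            class = "tpp_scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
default_scheme <- function() {
  scoring_scheme(
    level_codes = c(met_preferred = 3, met_minimum = 2, partial_minimum = 1,
                    not_met = 0, unknown = 0),
    weights = stats::setNames(ifelse(tpp_parameters() %in% c("efficacy", "safety"),
                                     2, 1), tpp_parameters()),
    thresholds = stats::setNames(
      rep(list(list(high_cut = 0.70, medium_cut = 0.40)), 3),
      tpp_rankable_phases()),
    unknown_policy = "score_zero"
  )
}

#' @rdname scoring_scheme
#' @param scheme A `tpp_scoring_scheme`.
#' @export
max_achievable <- function(scheme) {
  # every scale admits met_preferred, so the per-parameter maximum code is
  # the met_preferred code
  sum(scheme$weights) * scheme$level_codes[["met_preferred"]]
}

#' @export
print.tpp_scoring_scheme <- function(x, ...) {
  cat("<tpp_scoring_scheme>\n  codes:",
      paste(sprintf("%s=%g", names(x$level_codes), x$level_codes), collapse = " "),
      "\n  weights:",
      paste(sprintf("%s=%g", names(x$weights), x$weights), collapse = " "),
      "\n  cuts:",
      paste(vapply(names(x$thresholds), function(p)
        sprintf("%s high>=%.2f med>=%.2f", p, x$thresholds[[p]]$high_cut,
                x$thresholds[[p]]$medium_cut), character(1)), collapse = "; "),
      "\n  unknown policy:", x$unknown_policy, "\n")
  invisible(x)
}

#' Read/write a scoring scheme config file
#'
#' Structured-text (JSON) config with keys `level_codes`, `weights`,
#' `thresholds.phaseN.{high_cut,medium_cut}` and `unknown_policy`.
#' A scheme round-trips exactly: the reloaded scheme scores every sheet
#' identically.
#'
#' @param path Config file path.
#' @return `read_scheme()` returns a validated `tpp_scoring_scheme`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) tpp_error("tpp_io_error", paste0("file not found: ", path))
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  scoring_scheme(level_codes = unlist(obj$level_codes),
                 weights = unlist(obj$weights),
                 thresholds = obj$thresholds,
                 unknown_policy = obj$unknown_policy %||% "score_zero")
}

#' @rdname read_scheme
#' @param scheme A `tpp_scoring_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "tpp_scoring_scheme"))
  jsonlite::write_json(list(
    level_codes = as.list(scheme$level_codes),
    weights = as.list(scheme$weights),
    thresholds = scheme$thresholds,
    unknown_policy = scheme$unknown_policy
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score an adjudicated rating sheet
#'
#' The weighted score is the sum over parameters of
#' `weight[p] * code[level(p)]`. Under the `exclude_and_renormalize` policy,
#' parameters rated `unknown` are dropped from both the score and the
#' achievable maximum (an all-unknown sheet is then undefined and raises a
#' `tpp_degenerate_error`).
#'
#' @param sheet A validated, fully adjudicated `tpp_rating_sheet` (a sheet
#'   flagged unresolved by [adjudicate()] raises a `tpp_usage_error`).
#' @param scheme A `tpp_scoring_scheme`; default [default_scheme()].
#' @return List with `weighted_score`, `max_achievable`, `score_fraction`
#'   and `breakdown` (data frame: parameter, level, code, weight,
#'   contribution, included).
#' @examples
#' sh <- rating_sheet("x", "consensus",
#'   stats::setNames(rep("met_preferred", 9), tpp_parameters()))
#' score_sheet(sh)$weighted_score
#' @export
score_sheet <- function(sheet, scheme = default_scheme()) {
  if (isTRUE(attr(sheet, "unresolved")) || anyNA(sheet$levels)) {
    tpp_error("tpp_usage_error",
              "sheet has unresolved disagreements and cannot be scored")
  }
  validate_sheet(sheet)
  stopifnot(inherits(scheme, "tpp_scoring_scheme"))
  params <- tpp_parameters()
  levels <- sheet$levels[params]
  codes <- scheme$level_codes[levels]
  weights <- scheme$weights[params]
  included <- rep(TRUE, length(params))
  if (scheme$unknown_policy == "exclude_and_renormalize") {
    included <- levels != "unknown"
    if (!any(included)) {
      tpp_error("tpp_degenerate_error",
                "all nine parameters are unknown; score undefined under exclude_and_renormalize")
    }
  }
  contribution <- unname(weights * codes) * included
  weighted_score <- sum(contribution)
  maxima <- weights * scheme$level_codes[["met_preferred"]]
  max_ach <- sum(maxima[included])
  list(
    weighted_score = weighted_score,
    max_achievable = max_ach,
    score_fraction = weighted_score / max_ach,
    breakdown = data.frame(parameter = params, level = unname(levels),
                           code = unname(codes), weight = unname(weights),
                           contribution = contribution, included = included,
                           stringsAsFactors = FALSE)
  )
}

#' Map a score fraction to a potential tier
#'
#' Step function with two breakpoints per phase; boundary values belong to
#' the upper tier (`>=` comparisons). Only Phase I-III candidates are
#' rankable; other phases raise a `tpp_usage_error`.
#'
#' @param score_fraction Numeric in \[0, 1\] (vectorized).
#' @param phase One of `"phase1"`, `"phase2"`, `"phase3"`.
#' @param scheme A `tpp_scoring_scheme`.
#' @return Character vector over `{"high","medium","low"}`.
#' @examples
#' rank_tier(c(0.39, 0.40, 0.69, 0.70), "phase2")
#' @export
rank_tier <- function(score_fraction, phase, scheme = default_scheme()) {
  if (length(phase) != 1L || !phase %in% tpp_rankable_phases()) {
    tpp_error("tpp_usage_error",
              paste0("ranking is defined for phases I-III only, not '",
                     paste(phase, collapse = ","), "'"))
  }
  if (any(is.na(score_fraction)) || any(score_fraction < 0 | score_fraction > 1)) {
    tpp_error("tpp_usage_error", "score_fraction must lie in [0, 1]")
  }
  cuts <- scheme$thresholds[[phase]]
  ifelse(score_fraction >= cuts$high_cut, "high",
         ifelse(score_fraction >= cuts$medium_cut, "medium", "low"))
}

#' Rank the screened-in clinical candidates of a registry
#'
#' Screens the registry (phases I-III), drops excluded candidates, matches
#' each survivor to its adjudicated consensus sheet, scores and tiers it,
#' and tallies the tiers. Candidates without a sheet are reported in
#' `missing` with a warning and excluded from the tally.
#'
#' @param reg A `tpp_registry`.
#' @param sheets List of adjudicated `tpp_rating_sheet`s (one per candidate;
#'   rater id conventionally `"consensus"`).
#' @param scheme A `tpp_scoring_scheme`.
#' @param phases Phases to rank (default phases I-III).
#' @return List with `results` (data frame: candidate_id, name, phase,
#'   weighted_score, max_achievable, score_fraction, tier), `tally`
#'   (named counts high/medium/low) and `missing` (candidate ids lacking a
#'   sheet).
#' @export
rank_registry <- function(reg, sheets, scheme = default_scheme(),
                          phases = tpp_rankable_phases()) {
  validate_registry(reg)
  bad <- setdiff(phases, tpp_rankable_phases())
  if (length(bad)) {
    tpp_error("tpp_usage_error",
              paste0("cannot rank phase(s): ", paste(bad, collapse = ", ")))
  }
  screened <- screen_registry(reg, phases = phases)
  keep_ids <- screened$decisions$candidate_id[!screened$decisions$excluded]
  df <- reg$candidates
  df <- df[df$id %in% keep_ids, , drop = FALSE]
  by_id <- stats::setNames(sheets, vapply(sheets, `[[`, character(1), "candidate_id"))
  rows <- list(); missing <- character()
  for (i in seq_len(nrow(df))) {
    cid <- df$id[i]
    sheet <- by_id[[cid]]
    if (is.null(sheet)) { missing <- c(missing, cid); next }
    sc <- score_sheet(sheet, scheme)
    rows[[length(rows) + 1L]] <- data.frame(
      candidate_id = cid, name = df$name[i], phase = df$phase[i],
      weighted_score = sc$weighted_score, max_achievable = sc$max_achievable,
      score_fraction = sc$score_fraction,
      tier = rank_tier(sc$score_fraction, df$phase[i], scheme),
      stringsAsFactors = FALSE)
  }
  if (length(missing)) {
    warning(sprintf("no adjudicated sheet for %d candidate(s): %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate_id = character(), name = character(),
               phase = character(), weighted_score = numeric(),
               max_achievable = numeric(), score_fraction = numeric(),
               tier = character(), stringsAsFactors = FALSE)
  list(results = results, tally = tally_tiers(results$tier), missing = missing)
}

#' Tally potential tiers
#'
#' @param tiers Character vector over `{"high","medium","low"}` (or a data
#'   frame with a `tier` column).
#' @return Named integer vector `c(high=, medium=, low=)`.
#' @export
tally_tiers <- function(tiers) {
  if (is.data.frame(tiers)) tiers <- tiers$tier
  bad <- setdiff(unique(tiers), c("high", "medium", "low"))
  if (length(bad)) {
    tpp_error("tpp_value_error",
              paste0("unknown tier token(s): ", paste(bad, collapse = ", ")))
  }
  vapply(c(high = "high", medium = "medium", low = "low"),
         function(t) sum(tiers == t), integer(1))
}
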