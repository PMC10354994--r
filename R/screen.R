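# Eligibility screen: ordered exclusion criteria C1..C6 and flow accounting.
#
# C1 marketed_for_indication    approved and on the market for this indication
# C2 who_recommended_or_routine WHO-recommended or otherwise in routine use
# C3 subgroup_recommended       already recommended/widely used in a subgroup
# C4 halted_negative_outcomes   inactive due to negative trial outcomes
# C5 inferior_to_current        indicated as inferior to current treatments
# C6 other_labour_indication    investigated for other labour/birth indications

screen_criteria <- function() paste0("C", 1:6)

#' Screen one candidate against the six exclusion criteria
#'
#' Each eligibility-evidence flag maps index-wise to a criterion (the flag
#' order of [eligibility_flags()] is C1..C6). A candidate is excluded iff at
#' least one flag is true; all applicable criteria are recorded and the
#' lowest-numbered one is reported as primary, matching the ordered listing
#' of the criteria.
#'
#' @param candidate A single-row candidate data frame or named list carrying
#'   the six flag fields (and optionally `id`).
#' @return A list of class `tpp_screen_decision` with `candidate_id`,
#'   `excluded`, `criteria_met` (character subset of C1..C6) and
#'   `primary_criterion` (`NA` when not excluded).
#' @examples
#' cand <- example_candidates(1)
#' cand$who_recommended_or_routine <- TRUE
#' screen_candidate(cand)$primary_criterion
#' @export
screen_candidate <- function(candidate) {
  flags <- vapply(eligibility_flags(), function(f) {
    v <- candidate[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      tpp_error("tpp_schema_error",
                paste0("eligibility flag `", f, "` must be a single TRUE/FALSE"))
    }
    as.logical(v)
  }, logical(1))
  met <- screen_criteria()[flags]
  structure(list(
    candidate_id = as.character(candidate[["id"]] %||% NA_character_),
    excluded = length(met) > 0L,
    criteria_met = met,
    primary_criterion = if (length(met)) met[[1L]] else NA_character_
  ), class = "tpp_screen_decision")
}

#' Screen a registry and account for the attrition flow
#'
#' Applies [screen_candidate()] to every candidate in the selected phases and
#' tallies a flowchart-style report: how many entered, how many were excluded
#' under each primary criterion, and how many remain.
#'
#' @param reg A `tpp_registry`.
#' @param phases Phases to screen; default the four clinical phases.
#' @return A list with `decisions` (data frame: `candidate_id`, `excluded`,
#'   `criteria_met` comma-joined, `primary_criterion`) and `report`
#'   (`tpp_flow_report`: `n_total`, `n_clinical`, `n_excluded`, `n_remaining`,
#'   `per_criterion_counts`).
#' @export
screen_registry <- function(reg, phases = tpp_clinical_phases()) {
  validate_registry(reg)
  if (!length(phases)) tpp_error("tpp_usage_error", "`phases` must be non-empty")
  bad <- setdiff(phases, tpp_phases())
  if (length(bad)) {
    tpp_error("tpp_value_error",
              paste0("unknown phase token(s): ", paste(bad, collapse = ", ")))
  }
  df <- reg$candidates
  sel <- df[df$phase %in% phases, , drop = FALSE]
  decisions <- if (nrow(sel)) {
    rows <- lapply(seq_len(nrow(sel)), function(i) {
      d <- screen_candidate(sel[i, , drop = FALSE])
      data.frame(candidate_id = d$candidate_id, excluded = d$excluded,
                 criteria_met = paste(d$criteria_met, collapse = ","),
                 primary_criterion = d$primary_criterion,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    data.frame(candidate_id = character(), excluded = logical(),
               criteria_met = character(), primary_criterion = character(),
               stringsAsFactors = FALSE)
  }
  per <- vapply(screen_criteria(), function(cr) {
    sum(!is.na(decisions$primary_criterion) & decisions$primary_criterion == cr)
  }, integer(1))
  report <- structure(list(
    n_total = nrow(df),
    n_clinical = nrow(sel),
    n_excluded = sum(decisions$excluded),
    n_remaining = nrow(sel) - sum(decisions$excluded),
    per_criterion_counts = per
  ), class = "tpp_flow_report")
  stopifnot(report$n_remaining == report$n_clinical - report$n_excluded,
            sum(report$per_criterion_counts) == report$n_excluded)
  list(decisions = decisions, report = report)
}

#' @export
print.tpp_flow_report <- function(x, ...) {
  cat(sprintf("<tpp_flow_report> total=%d screened=%d excluded=%d remaining=%d\n",
              x$n_total, x$n_clinical, x$n_excluded, x$n_remaining))
  pc <- x$per_criterion_counts
  cat("  primary criterion:",
      paste(sprintf("%s=%d", names(pc), pc), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.tpp_screen_decision <- function(x, ...) {
  cat(sprintf("<screen decision> %s: %s%s\n", x$candidate_id,
              if (x$excluded) "EXCLUDED" else "retained",
              if (x$excluded) paste0(" [", paste(x$criteria_met, collapse = ","),
                                     "; primary ", x$primary_criterion, "]")
              else ""))
  invisible(x)
}

#' Serialize a flow report to JSON
#'
#' @param report A `tpp_flow_report`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_flow_report <- function(report, path) {
  stopifnot(inherits(report, "tpp_flow_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
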