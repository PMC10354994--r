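# TPP rating model: nine critical parameters, ordinal rating levels with
# three scale kinds, dual-rater sheets, adjudication, agreement.

#' The nine critical TPP parameters
#'
#' Canonical order: setting, efficacy, companion_diagnostic,
#' clinical_monitoring, safety, administration, adherence, stability,
#' eml_listing. `setting` is rated on a three-level country-setting scale,
#' `stability` and `eml_listing` on a binary-with-unknown scale, the rest on
#' the full five-level ordinal scale. Efficacy and safety are the weighted
#' parameters.
#'
#' @return Character vector of the nine parameter names.
#' @export
tpp_parameters <- function() {
  c("setting", "efficacy", "companion_diagnostic", "clinical_monitoring",
    "safety", "administration", "adherence", "stability", "eml_listing")
}

#' @rdname tpp_parameters
#' @export
parameter_scales <- function() {
  c(setting = "setting3", efficacy = "ordinal5",
    companion_diagnostic = "ordinal5", clinical_monitoring = "ordinal5",
    safety = "ordinal5", administration = "ordinal5", adherence = "ordinal5",
    stability = "binary_unknown", eml_listing = "binary_unknown")
}

#' Rating levels and admissibility
#'
#' The five canonical levels are `met_preferred`, `met_minimum`,
#' `partial_minimum`, `not_met`, `unknown`. The restricted scales admit a
#' subset: the setting scale admits both-settings (`met_preferred`),
#' single-setting (`partial_minimum`) and not-stated (`unknown`); the
#' binary-with-unknown scale admits `met_preferred` (met), `not_met` and
#' `unknown`. Domain aliases `both_settings`, `single_setting`, `not_stated`
#' and `met` are accepted on input and normalized to the canonical tokens.
#'
#' @return `rating_levels()`: the five canonical tokens.
#' @export
rating_levels <- function() {
  c("met_preferred", "met_minimum", "partial_minimum", "not_met", "unknown")
}

scale_levels <- function() {
  list(
    ordinal5 = rating_levels(),
    setting3 = c("met_preferred", "partial_minimum", "unknown"),
    binary_unknown = c("met_preferred", "not_met", "unknown")
  )
}

# Worst-to-best ladders used by monotonicity reasoning and the generators.
scale_ladders <- function() {
  list(
    ordinal5 = c("unknown", "not_met", "partial_minimum", "met_minimum",
                 "met_preferred"),
    setting3 = c("unknown", "partial_minimum", "met_preferred"),
    binary_unknown = c("unknown", "not_met", "met_preferred")
  )
}

#' @rdname rating_levels
#' @param parameter One of [tpp_parameters()].
#' @export
admissible_levels <- function(parameter) {
  scales <- parameter_scales()
  if (!parameter %in% names(scales)) {
    tpp_error("tpp_value_error", paste0("unknown TPP parameter: ", parameter))
  }
  scale_levels()[[scales[[parameter]]]]
}

level_aliases <- function() {
  c(both_settings = "met_preferred", single_setting = "partial_minimum",
    not_stated = "unknown", met = "met_preferred")
}

normalize_levels <- function(levels) {
  al <- level_aliases()
  hit <- levels %in% names(al)
  levels[hit] <- al[levels[hit]]
  levels
}

#' Construct a rating sheet
#'
#' One rater's nine TPP-parameter levels for one candidate. Levels are
#' normalized (aliases resolved) and validated for scale admissibility.
#'
#' @param candidate_id Candidate identifier.
#' @param rater_id Rater identifier (e.g. `"rater_a"`, `"consensus"`).
#' @param levels Named character vector or list mapping every parameter of
#'   [tpp_parameters()] to an admissible level.
#' @return Object of class `tpp_rating_sheet`.
#' @examples
#' sh <- rating_sheet("x", "rater_a",
#'   stats::setNames(rep("met_preferred", 9), tpp_parameters()))
#' agreement_rate(sh, sh)
#' @export
rating_sheet <- function(candidate_id, rater_id, levels) {
  levels <- unlist(levels)
  sheet <- structure(list(
    candidate_id = as.character(candidate_id),
    rater_id = as.character(rater_id),
    levels = normalize_levels(stats::setNames(as.character(levels), names(levels)))
  ), class = "tpp_rating_sheet")
  validate_sheet(sheet)
}

#' Validate a rating sheet
#'
#' Checks that all nine parameters are present and that every level is
#' admissible for its parameter's scale. Missing parameters raise a
#' `tpp_schema_error`; inadmissible levels (e.g. `met_minimum` on the WHO
#' EML parameter, which is binary) raise a `tpp_value_error` naming the
#' parameter and level.
#'
#' @param sheet A `tpp_rating_sheet`.
#' @return `sheet`, unchanged, when valid.
#' @export
validate_sheet <- function(sheet) {
  stopifnot(inherits(sheet, "tpp_rating_sheet"))
  params <- tpp_parameters()
  missing <- setdiff(params, names(sheet$levels))
  if (length(missing)) {
    tpp_error("tpp_schema_error",
              paste0("rating sheet missing parameter(s): ",
                     paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(sheet$levels), params)
  if (length(extra)) {
    tpp_error("tpp_schema_error",
              paste0("unknown parameter(s): ", paste(extra, collapse = ", ")))
  }
  sheet$levels <- sheet$levels[params]
  for (p in params) {
    lv <- sheet$levels[[p]]
    if (is.na(lv) || !lv %in% admissible_levels(p)) {
      tpp_error("tpp_value_error",
                sprintf("level '%s' is not admissible for parameter '%s' (scale %s)",
                        lv, p, parameter_scales()[[p]]))
    }
  }
  sheet
}

#' @export
print.tpp_rating_sheet <- function(x, ...) {
  cat(sprintf("<tpp_rating_sheet> candidate=%s rater=%s\n",
              x$candidate_id, x$rater_id))
  for (p in tpp_parameters()) cat(sprintf("  %-22s %s\n", p, x$levels[[p]]))
  invisible(x)
}

check_same_candidate <- function(a, b) {
  stopifnot(inherits(a, "tpp_rating_sheet"), inherits(b, "tpp_rating_sheet"))
  if (!identical(a$candidate_id, b$candidate_id)) {
    tpp_error("tpp_usage_error",
              sprintf("sheets rate different candidates ('%s' vs '%s')",
                      a$candidate_id, b$candidate_id))
  }
}

#' Merge two independent raters with third-rater resolution
#'
#' Parameters on which the raters agree are copied through to the consensus
#' sheet. Disagreements take the third rater's level where provided; any
#' disagreement not covered by `third` leaves the merged level undefined and
#' flags the result unresolved (an unresolved result cannot be scored).
#'
#' @param sheet_a,sheet_b Two validated `tpp_rating_sheet`s for the same
#'   candidate.
#' @param third Optional named character vector/list of third-rater levels
#'   for (a subset of) the disagreeing parameters.
#' @return Object of class `tpp_adjudication`: list with `merged`
#'   (consensus `tpp_rating_sheet`), `disagreements` (data frame `parameter`,
#'   `level_a`, `level_b`), `resolved_by_third` (character) and `unresolved`
#'   (logical).
#' @export
adjudicate <- function(sheet_a, sheet_b, third = NULL) {
  check_same_candidate(sheet_a, sheet_b)
  validate_sheet(sheet_a); validate_sheet(sheet_b)
  params <- tpp_parameters()
  la <- sheet_a$levels[params]; lb <- sheet_b$levels[params]
  disagree <- params[la != lb]
  third <- if (is.null(third)) character() else {
    tl <- normalize_levels(stats::setNames(as.character(unlist(third)),
                                           names(unlist(third))))
    for (p in names(tl)) {
      if (!p %in% params) {
        tpp_error("tpp_value_error", paste0("unknown parameter in third map: ", p))
      }
      if (!tl[[p]] %in% admissible_levels(p)) {
        tpp_error("tpp_value_error",
                  sprintf("third-rater level '%s' inadmissible for '%s'", tl[[p]], p))
      }
    }
    tl
  }
  merged <- la
  unresolved_params <- character()
  for (p in disagree) {
    if (p %in% names(third)) {
      merged[[p]] <- third[[p]]
    } else {
      merged[[p]] <- NA_character_
      unresolved_params <- c(unresolved_params, p)
    }
  }
  unresolved <- length(unresolved_params) > 0L
  merged_sheet <- structure(list(
    candidate_id = sheet_a$candidate_id, rater_id = "consensus",
    levels = merged), class = "tpp_rating_sheet")
  if (!unresolved) merged_sheet <- validate_sheet(merged_sheet)
  attr(merged_sheet, "unresolved") <- unresolved
  structure(list(
    merged = merged_sheet,
    disagreements = data.frame(parameter = disagree,
                               level_a = unname(la[disagree]),
                               level_b = unname(lb[disagree]),
                               stringsAsFactors = FALSE),
    resolved_by_third = intersect(disagree, names(third)),
    unresolved = unresolved,
    unresolved_parameters = unresolved_params
  ), class = "tpp_adjudication")
}

#' Inter-rater agreement rate
#'
#' Fraction of the nine parameters on which two raters assigned the same
#' level.
#'
#' @param sheet_a,sheet_b Two validated sheets for the same candidate.
#' @return A number in \[0, 1\].
#' @export
agreement_rate <- function(sheet_a, sheet_b) {
  check_same_candidate(sheet_a, sheet_b)
  validate_sheet(sheet_a); validate_sheet(sheet_b)
  params <- tpp_parameters()
  mean(sheet_a$levels[params] == sheet_b$levels[params])
}

# ---- sheet collection I/O -------------------------------------------------
# Wide CSV: candidate_id, rater_id, then one column per parameter.
# JSON: {"sheets":[{"candidate_id":..., "rater_id":..., "levels":{...}}]}

#' Read or write collections of rating sheets
#'
#' @param path File path; CSV is wide (one column per parameter), JSON is a
#'   `sheets` array of objects with a `levels` map.
#' @param format `"csv"`, `"json"`, or `"auto"`.
#' @return `load_sheets()` returns a list of `tpp_rating_sheet`s.
#' @export
load_sheets <- function(path, format = "auto") {
  if (!file.exists(path)) tpp_error("tpp_io_error", paste0("file not found: ", path))
  format <- guess_format(path, format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
    need <- c("candidate_id", "rater_id", tpp_parameters())
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      tpp_error("tpp_schema_error",
                paste0("sheet file missing column(s): ",
                       paste(missing, collapse = ", ")))
    }
    lapply(seq_len(nrow(df)), function(i) {
      rating_sheet(df$candidate_id[i], df$rater_id[i],
                   stats::setNames(as.character(df[i, tpp_parameters()]),
                                   tpp_parameters()))
    })
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    lapply(obj$sheets, function(s) {
      rating_sheet(s$candidate_id, s$rater_id, unlist(s$levels))
    })
  }
}

#' @rdname load_sheets
#' @param sheets List of `tpp_rating_sheet`s.
#' @export
write_sheets <- function(sheets, path, format = "auto") {
  stopifnot(all(vapply(sheets, inherits, logical(1), "tpp_rating_sheet")))
  format <- guess_format(path, format)
  if (format == "csv") {
    rows <- lapply(sheets, function(s) {
      cbind(data.frame(candidate_id = s$candidate_id, rater_id = s$rater_id,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(s$levels[tpp_parameters()]),
                          stringsAsFactors = FALSE))
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(setNames(rep(list(character()), 11),
                             c("candidate_id", "rater_id", tpp_parameters())))
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(list(sheets = lapply(sheets, function(s) {
      list(candidate_id = s$candidate_id, rater_id = s$rater_id,
           levels = as.list(s$levels))
    })), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
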