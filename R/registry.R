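# Candidate-medicine registry: data model, validation, CSV/JSON I/O.

#' Closed vocabularies for registry fields
#'
#' Constant accessors for the enumerations used throughout the package:
#' development phases, indications, product types, archetypes, and the six
#' eligibility-evidence flags (in criterion order C1..C6).
#'
#' @return A character vector of admissible tokens.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
tpp_phases <- function() {
  c("preclinical", "phase1", "phase2", "phase3", "phase4", "marketed")
}

#' @rdname vocabularies
#' @export
tpp_clinical_phases <- function() c("phase1", "phase2", "phase3", "phase4")

#' @rdname vocabularies
#' @export
tpp_rankable_phases <- function() c("phase1", "phase2", "phase3")

#' @rdname vocabularies
#' @export
tpp_indications <- function() c("prevention", "management", "both")

#' @rdname vocabularies
#' @export
tpp_product_types <- function() c("drug", "biologic", "dietary_supplement")

#' @rdname vocabularies
#' @export
tpp_archetypes <- function() c("new_entity", "repurposed")

#' @rdname vocabularies
#' @export
eligibility_flags <- function() {
  c("marketed_for_indication", "who_recommended_or_routine",
    "subgroup_recommended", "halted_negative_outcomes",
    "inferior_to_current", "other_labour_indication")
}

registry_required_columns <- function() {
  c("id", "name", "indication", "phase", "product_type", "archetype",
    "last_update_year", "subclass", "route", eligibility_flags())
}

#' Construct a validated candidate registry
#'
#' A registry bundles a candidate table with the snapshot year of the
#' underlying database extract. Construction validates the closed enums,
#' id uniqueness, non-empty names, and year bounds; unknown extra columns
#' are retained untouched as opaque annotations.
#'
#' @param candidates Data frame with (at least) columns `id`, `name`,
#'   `indication`, `phase`, `product_type`, `archetype`, `last_update_year`
#'   (integer or `NA`), `subclass`, `route`, and the six logical
#'   eligibility-flag columns named by [eligibility_flags()].
#' @param snapshot_year Integer year of the registry snapshot (default 2021).
#' @return An object of class `tpp_registry`: a list with elements
#'   `candidates` (data frame) and `snapshot_year`.
#' @examples
#' reg <- registry(example_candidates(3))
#' nrow(reg$candidates)
#' @export
registry <- function(candidates, snapshot_year = 2021L) {
  if (!is.data.frame(candidates)) {
    tpp_error("tpp_schema_error", "`candidates` must be a data frame")
  }
  candidates <- coerce_candidate_columns(candidates)
  out <- structure(
    list(candidates = candidates, snapshot_year = as.integer(snapshot_year)),
    class = "tpp_registry"
  )
  validate_registry(out)
}

# Normalize column types without judging values (validation does that).
coerce_candidate_columns <- function(df) {
  required <- registry_required_columns()
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    tpp_error("tpp_schema_error",
              paste0("registry is missing required field(s): ",
                     paste(missing, collapse = ", ")))
  }
  chr_cols <- c("id", "name", "indication", "phase", "product_type",
                "archetype", "subclass", "route")
  for (col in chr_cols) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  yr <- df[["last_update_year"]]
  if (is.character(yr)) yr[yr == ""] <- NA_character_
  df[["last_update_year"]] <- suppressWarnings(as.integer(yr))
  for (col in eligibility_flags()) {
    v <- df[[col]]
    if (is.character(v)) v <- toupper(trimws(v)) %in% c("TRUE", "T", "1", "YES")
    df[[col]] <- as.logical(v)
    df[[col]][is.na(df[[col]])] <- FALSE
  }
  rownames(df) <- NULL
  # required columns first, annotations after, original order within each
  extra <- setdiff(names(df), required)
  df[, c(required, extra), drop = FALSE]
}

#' Validate a registry against its invariants
#'
#' Checks id uniqueness, non-empty names, enum membership and year bounds.
#' The first violated invariant raises a classed condition
#' (`tpp_schema_error`, `tpp_integrity_error` or `tpp_value_error`) whose
#' message names the offending row and token. Use [registry_problems()] for
#' a non-throwing per-row report.
#'
#' @param reg A `tpp_registry`.
#' @return `reg`, invisibly unchanged, if valid.
#' @export
validate_registry <- function(reg) {
  stopifnot(inherits(reg, "tpp_registry"))
  problems <- registry_problems(reg$candidates, reg$snapshot_year)
  if (nrow(problems)) {
    p <- problems[1L, ]
    tpp_error(p$class, sprintf("row %d, field `%s`: %s", p$row, p$field, p$problem))
  }
  reg
}

#' Per-row validation report for a candidate table
#'
#' @param candidates Candidate data frame (see [registry()]).
#' @param snapshot_year Snapshot year used for the year upper bound.
#' @return Data frame with columns `row`, `field`, `problem`, `class`;
#'   zero rows when the table is valid.
#' @export
registry_problems <- function(candidates, snapshot_year = 2021L) {
  out <- list()
  add <- function(row, field, problem, class) {
    out[[length(out) + 1L]] <<- data.frame(
      row = as.integer(row), field = field, problem = problem, class = class,
      stringsAsFactors = FALSE)
  }
  df <- candidates
  dup <- duplicated(df$id) | duplicated(df$id, fromLast = TRUE)
  for (i in which(duplicated(df$id))) {
    add(i, "id", sprintf("duplicate id '%s'", df$id[i]), "tpp_integrity_error")
  }
  bad_name <- is.na(df$name) | !nzchar(trimws(df$name))
  for (i in which(bad_name)) add(i, "name", "name is empty", "tpp_schema_error")
  enum_checks <- list(
    indication = tpp_indications(), phase = tpp_phases(),
    product_type = tpp_product_types(), archetype = tpp_archetypes())
  for (field in names(enum_checks)) {
    ok <- df[[field]] %in% enum_checks[[field]]
    for (i in which(!ok)) {
      add(i, field, sprintf("unparseable token '%s'", df[[field]][i]),
          "tpp_value_error")
    }
  }
  yr <- df$last_update_year
  bad_yr <- !is.na(yr) & (yr < 1900L | yr > as.integer(snapshot_year))
  for (i in which(bad_yr)) {
    add(i, "last_update_year",
        sprintf("year %d outside [1900, %d]", yr[i], as.integer(snapshot_year)),
        "tpp_value_error")
  }
  if (!length(out)) {
    return(data.frame(row = integer(), field = character(),
                      problem = character(), class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

guess_format <- function(path, format) {
  format <- match.arg(format, c("auto", "csv", "json"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}

#' Read a candidate registry from CSV or JSON
#'
#' The CSV dialect is UTF-8, comma-separated, quoted fields, one header row
#' with the exact field names of [registry_required_columns]; unknown extra
#' columns are retained. JSON carries a top-level `snapshot_year` and a
#' `candidates` array of per-candidate objects.
#'
#' @param path File to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (extension-based, default).
#' @return A validated `tpp_registry`; row order is preserved.
#' @seealso [write_registry()]
#' @export
load_registry <- function(path, format = "auto") {
  if (!file.exists(path)) {
    tpp_error("tpp_io_error", paste0("file not found: ", path))
  }
  format <- guess_format(path, format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
    snap <- attr(df, "snapshot_year") %||% 2021L
    registry(df, snapshot_year = snap)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    cand <- obj$candidates
    if (is.null(cand) || (!is.data.frame(cand) && length(cand) == 0)) {
      cand <- empty_candidate_frame()
    }
    registry(as.data.frame(cand, stringsAsFactors = FALSE),
             snapshot_year = obj$snapshot_year %||% 2021L)
  }
}

empty_candidate_frame <- function() {
  req <- registry_required_columns()
  df <- as.data.frame(setNames(rep(list(character()), length(req)), req),
                      stringsAsFactors = FALSE, check.names = FALSE)
  df$last_update_year <- integer()
  for (col in eligibility_flags()) df[[col]] <- logical()
  df
}

#' Write a candidate registry to CSV or JSON
#'
#' Inverse of [load_registry()]: `load_registry(write_registry(r, p), p)`
#' reproduces `r` field-for-field, including names containing commas or
#' quotes (CSV quoting) and absent years (empty cells / JSON nulls).
#'
#' @param reg A validated `tpp_registry`.
#' @param path Destination file.
#' @param format `"csv"`, `"json"`, or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path, format = "auto") {
  validate_registry(reg)
  format <- guess_format(path, format)
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(reg$candidates, path, row.names = FALSE, na = "",
                       fileEncoding = "UTF-8")
    } else {
      jsonlite::write_json(
        list(snapshot_year = reg$snapshot_year, candidates = reg$candidates),
        path, auto_unbox = TRUE, na = "null", digits = NA)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    tpp_error("tpp_io_error", paste0("cannot write ", path, ": ",
                                     conditionMessage(ok)))
  }
  invisible(path)
}

#' Is a candidate in active development?
#'
#' A candidate counts as active iff its last update year is known and is at
#' or after the cutoff year; an absent year counts inactive. The default
#' cutoff 2018 operationalizes "no updates since 2018".
#'
#' @param x A `tpp_registry`, a candidate data frame, a single-candidate list,
#'   or a vector of last-update years.
#' @param cutoff_year Positive integer cutoff (default 2018).
#' @return Logical vector, one element per candidate.
#' @examples
#' is_active(c(2020, 2017, NA))
#' @export
is_active <- function(x, cutoff_year = 2018L) {
  if (!is.numeric(cutoff_year) || length(cutoff_year) != 1L || cutoff_year <= 0) {
    tpp_error("tpp_usage_error", "`cutoff_year` must be a single positive integer")
  }
  years <- if (inherits(x, "tpp_registry")) {
    x$candidates$last_update_year
  } else if (is.data.frame(x) || is.list(x)) {
    x[["last_update_year"]]
  } else {
    x
  }
  years <- suppressWarnings(as.integer(years))
  !is.na(years) & years >= as.integer(cutoff_year)
}

#' @export
print.tpp_registry <- function(x, ...) {
  cat(sprintf("<tpp_registry> %d candidate(s), snapshot year %d\n",
              nrow(x$candidates), x$snapshot_year))
  tb <- table(factor(x$candidates$phase, levels = tpp_phases()))
  cat("  phases:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' Small example candidate table
#'
#' Convenience constructor used in examples and tests: `n` valid candidates
#' with deterministic field values and all eligibility flags `FALSE`.
#'
#' @param n Number of candidates.
#' @return A candidate data frame suitable for [registry()].
#' @export
example_candidates <- function(n = 3L) {
  n <- as.integer(n)
  if (n == 0L) return(empty_candidate_frame())
  df <- data.frame(
    id = sprintf("ex-%03d", seq_len(n)),
    name = sprintf("example candidate %d", seq_len(n)),
    indication = rep(c("prevention", "management", "both"), length.out = max(n, 1L))[seq_len(n)],
    phase = rep(tpp_phases()[1:5], length.out = max(n, 1L))[seq_len(n)],
    product_type = rep(tpp_product_types(), length.out = max(n, 1L))[seq_len(n)],
    archetype = rep(tpp_archetypes(), length.out = max(n, 1L))[seq_len(n)],
    last_update_year = rep(c(2020L, 2015L, NA_integer_), length.out = max(n, 1L))[seq_len(n)],
    subclass = "Unspecified",
    route = "Oral",
    stringsAsFactors = FALSE
  )
  for (col in eligibility_flags()) df[[col]] <- FALSE
  df
}
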