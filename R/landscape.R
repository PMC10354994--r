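# Landscape statistics: marginal count/percentage tables, subclass
# frequency tables, dual-indication detection.

#' One-decimal percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal — the
#' convention that reproduces the published marginal percentages (e.g.
#' 68/178 -> 38.2, 14/36 -> 38.9, 12/58 -> 20.7). Note base R's `round()`
#' rounds half-to-even and would not.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0` (vectorized; recycled).
#' @return Numeric percentage(s) with one decimal place.
#' @examples
#' percent1(68, 178)
#' @export
percent1 <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    tpp_error("tpp_degenerate_error", "percentage undefined for denominator 0")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    tpp_error("tpp_usage_error", "need 0 <= numerator <= denominator")
  }
  floor(1000 * numerator / denominator + 0.5) / 10
}

count_table <- function(values, levels, total) {
  counts <- vapply(levels, function(l) sum(values == l), integer(1))
  data.frame(level = levels, count = unname(counts),
             percentage = if (total > 0) percent1(unname(counts), total) else numeric(length(levels)),
             stringsAsFactors = FALSE)
}

#' Marginal landscape summary of a registry
#'
#' Counts and one-decimal percentages by activity status, development phase,
#' product type and archetype. Deterministic and invariant to candidate
#' order.
#'
#' @param reg A `tpp_registry`.
#' @param cutoff_year Activity cutoff year passed to [is_active()].
#' @return Object of class `tpp_landscape`: list with `total` and data
#'   frames `by_status`, `by_phase`, `by_product_type`, `by_archetype`
#'   (columns `level`, `count`, `percentage`).
#' @export
summarize_registry <- function(reg, cutoff_year = 2018L) {
  validate_registry(reg)
  df <- reg$candidates
  total <- nrow(df)
  if (total == 0L) {
    empty <- data.frame(level = character(), count = integer(),
                        percentage = numeric(), stringsAsFactors = FALSE)
    return(structure(list(total = 0L, by_status = empty, by_phase = empty,
                          by_product_type = empty, by_archetype = empty),
                     class = "tpp_landscape"))
  }
  status <- ifelse(is_active(reg, cutoff_year), "active", "inactive")
  structure(list(
    total = total,
    by_status = count_table(status, c("active", "inactive"), total),
    by_phase = count_table(df$phase, tpp_phases(), total),
    by_product_type = count_table(df$product_type, tpp_product_types(), total),
    by_archetype = count_table(df$archetype, tpp_archetypes(), total)
  ), class = "tpp_landscape")
}

#' @export
print.tpp_landscape <- function(x, ...) {
  cat(sprintf("<tpp_landscape> %d candidate(s)\n", x$total))
  for (nm in c("by_status", "by_phase", "by_product_type", "by_archetype")) {
    tb <- x[[nm]]
    tb <- tb[tb$count > 0, , drop = FALSE]
    cat(" ", sub("^by_", "", nm), ": ",
        paste(sprintf("%s %d (%.1f%%)", tb$level, tb$count, tb$percentage),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# percentage lookup helper used by tests/acceptance
landscape_pct <- function(summary, table, level) {
  tb <- summary[[table]]
  tb$percentage[tb$level == level]
}

#' Medicine-subclass frequency table for one indication scope
#'
#' Candidates with indication `both` contribute to both scopes. Rows are
#' sorted by descending count, ties broken alphabetically; percentages are
#' over the scope total.
#'
#' @param reg A `tpp_registry`.
#' @param scope `"prevention"` or `"management"`.
#' @return Data frame with columns `subclass`, `count`, `percentage`;
#'   zero rows when the scope is empty.
#' @export
subclass_frequency <- function(reg, scope = c("prevention", "management")) {
  scope <- match.arg(scope)
  validate_registry(reg)
  df <- reg$candidates
  sel <- df[df$indication %in% c(scope, "both"), , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(subclass = character(), count = integer(),
                      percentage = numeric(), stringsAsFactors = FALSE))
  }
  sub <- trimws(ifelse(is.na(sel$subclass), "Unspecified", sel$subclass))
  tb <- table(sub)
  out <- data.frame(subclass = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$subclass), , drop = FALSE]
  out$percentage <- percent1(out$count, nrow(sel))
  rownames(out) <- NULL
  out
}

#' Candidates evaluated for both prevention and management
#'
#' Detects dual-indication candidates either via an explicit `both`
#' indication or via the same (case-folded) name appearing under both the
#' prevention and management scopes, as happens when per-scope tables are
#' merged into one registry.
#'
#' @param reg A `tpp_registry`.
#' @return Character vector of candidate names (original casing, unique).
#' @export
dual_indication <- function(reg) {
  validate_registry(reg)
  df <- reg$candidates
  explicit <- df$name[df$indication == "both"]
  key <- tolower(trimws(df$name))
  prev <- unique(key[df$indication == "prevention"])
  mgmt <- unique(key[df$indication == "management"])
  cross <- intersect(prev, mgmt)
  out <- c(explicit, df$name[key %in% cross])
  out[!duplicated(tolower(trimws(out)))]
}
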