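# Traffic-light matrix: per-cell color tokens plus a final-rank column,
# exported as CSV (round-trippable tokens), SVG or HTML.

TPP_COLORS <- c(dark_green = "#1a7a1a", light_green = "#7fc97f",
                yellow = "#f2d22e", red = "#d64545", grey = "#bdbdbd")
TIER_COLORS <- c(high = "#1a7a1a", medium = "#f2d22e", low = "#d64545")

#' Map a (parameter, level) pair to its legend color token
#'
#' Full ordinal scale: met preferred -> `dark_green`, met minimum ->
#' `light_green`, partially met minimum -> `yellow`, not met -> `red`,
#' not yet known -> `grey`. The country-setting scale maps both settings ->
#' `dark_green`, single setting -> `yellow`, not stated -> `grey`. Cold-chain
#' stability and WHO EML listing map met -> green (rendered with the
#' `light_green` token), not met -> `red`, unsure -> `grey`.
#'
#' @param parameter Parameter name(s) from [tpp_parameters()] (vectorized).
#' @param level Admissible level(s) for that parameter's scale.
#' @return Color token(s) in `{dark_green, light_green, yellow, red, grey}`.
#' @examples
#' color_map("efficacy", "met_preferred")
#' color_map("setting", "single_setting")
#' @export
color_map <- function(parameter, level) {
  n <- max(length(parameter), length(level))
  parameter <- rep_len(parameter, n); level <- rep_len(normalize_levels(level), n)
  maps <- list(
    ordinal5 = c(met_preferred = "dark_green", met_minimum = "light_green",
                 partial_minimum = "yellow", not_met = "red", unknown = "grey"),
    setting3 = c(met_preferred = "dark_green", partial_minimum = "yellow",
                 unknown = "grey"),
    binary_unknown = c(met_preferred = "light_green", not_met = "red",
                       unknown = "grey")
  )
  scales <- parameter_scales()
  vapply(seq_len(n), function(i) {
    p <- parameter[[i]]; l <- level[[i]]
    if (!p %in% names(scales)) {
      tpp_error("tpp_value_error", paste0("unknown TPP parameter: ", p))
    }
    if (!l %in% admissible_levels(p)) {
      tpp_error("tpp_value_error",
                sprintf("level '%s' inadmissible for parameter '%s'", l, p))
    }
    maps[[scales[[p]]]][[l]]
  }, character(1))
}

#' Build the candidate-by-parameter traffic-light matrix
#'
#' One row per ranked candidate, ten columns (nine parameters + final rank).
#' Rows are ordered deterministically the way the published figures are laid
#' out: phase descending (III, II, I), then score fraction descending, then
#' name.
#'
#' @param rank_results Data frame as returned in `rank_registry()$results`.
#' @param sheets List of the adjudicated `tpp_rating_sheet`s backing those
#'   results. Every result must have a matching sheet and vice versa.
#' @return Object of class `tpp_matrix`: list with `rows` (data frame:
#'   candidate_id, name, phase, tier), `parameters`, and `cells` (character
#'   matrix, one color token per parameter cell).
#' @export
build_matrix <- function(rank_results, sheets) {
  sheet_ids <- vapply(sheets, `[[`, character(1), "candidate_id")
  orphan_results <- setdiff(rank_results$candidate_id, sheet_ids)
  orphan_sheets <- setdiff(sheet_ids, rank_results$candidate_id)
  if (length(orphan_results) || length(orphan_sheets)) {
    tpp_error("tpp_integrity_error",
              paste0("results/sheets mismatch; results without sheet: [",
                     paste(orphan_results, collapse = ", "),
                     "]; sheets without result: [",
                     paste(orphan_sheets, collapse = ", "), "]"))
  }
  ord <- order(-match(rank_results$phase, tpp_rankable_phases()),
               -rank_results$score_fraction, rank_results$name)
  res <- rank_results[ord, , drop = FALSE]
  by_id <- stats::setNames(sheets, sheet_ids)
  params <- tpp_parameters()
  cells <- matrix(NA_character_, nrow = nrow(res), ncol = length(params),
                  dimnames = list(NULL, params))
  for (i in seq_len(nrow(res))) {
    sheet <- by_id[[res$candidate_id[i]]]
    cells[i, ] <- color_map(params, unname(sheet$levels[params]))
  }
  structure(list(
    rows = data.frame(candidate_id = res$candidate_id, name = res$name,
                      phase = res$phase, tier = res$tier,
                      stringsAsFactors = FALSE),
    parameters = params,
    cells = cells
  ), class = "tpp_matrix")
}

#' @export
print.tpp_matrix <- function(x, ...) {
  cat(sprintf("<tpp_matrix> %d row(s) x %d column(s) (+ final rank)\n",
              nrow(x$cells), ncol(x$cells)))
  invisible(x)
}

#' Export a traffic-light matrix
#'
#' CSV emits the raw color tokens (and re-imports to an identical grid via
#' [read_matrix_csv()]); SVG emits one `<rect>` per cell (including the
#' final-rank cell) with a legend text block; HTML emits a colored table.
#'
#' @param matrix A `tpp_matrix`.
#' @param path Destination file.
#' @param format `"csv"`, `"svg"` or `"html"`.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(matrix, path, format = c("csv", "svg", "html")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "tpp_matrix"))
  out <- tryCatch({
    switch(format,
           csv = export_matrix_csv(matrix, path),
           svg = export_matrix_svg(matrix, path),
           html = export_matrix_html(matrix, path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(out)) {
    tpp_error("tpp_io_error",
              paste0("cannot write ", path, ": ", conditionMessage(out)))
  }
  invisible(path)
}

export_matrix_csv <- function(matrix, path) {
  df <- cbind(matrix$rows[, c("candidate_id", "name", "phase"), drop = FALSE],
              as.data.frame(matrix$cells, stringsAsFactors = FALSE),
              data.frame(final_rank = matrix$rows$tier, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname export_matrix
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) tpp_error("tpp_io_error", paste0("file not found: ", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("candidate_id", "name", "phase", tpp_parameters(), "final_rank")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    tpp_error("tpp_schema_error",
              paste0("matrix file missing column(s): ",
                     paste(missing, collapse = ", ")))
  }
  cells <- as.matrix(df[, tpp_parameters(), drop = FALSE])
  dimnames(cells) <- list(NULL, tpp_parameters())
  structure(list(
    rows = data.frame(candidate_id = df$candidate_id, name = df$name,
                      phase = df$phase, tier = df$final_rank,
                      stringsAsFactors = FALSE),
    parameters = tpp_parameters(),
    cells = cells
  ), class = "tpp_matrix")
}

matrix_legend_lines <- function() {
  c("met preferred = dark green; met minimum = light green;",
    "partially met minimum = yellow; did not meet minimum = red;",
    "not yet known = grey.",
    "Setting: both HIC and LMIC = dark green; HIC only or LMIC only = yellow;",
    "country not stated = grey.",
    "Stability: no cold chain = green; cold chain required = red; unsure = grey.",
    "WHO EML: listed = green; not listed = red.")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

export_matrix_svg <- function(matrix, path) {
  cell <- 22; pad_left <- 240; pad_top <- 40
  n <- nrow(matrix$cells); ncols <- length(matrix$parameters) + 1L
  legend_h <- 16 * (length(matrix_legend_lines()) + 1)
  width <- pad_left + ncols * cell + 20
  height <- pad_top + n * cell + legend_h + 30
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf("<!-- color table: %s; final rank: %s -->",
            paste(sprintf("%s=%s", names(TPP_COLORS), TPP_COLORS), collapse = " "),
            paste(sprintf("%s=%s", names(TIER_COLORS), TIER_COLORS), collapse = " ")),
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height))
  # column headers
  for (j in seq_len(ncols)) {
    label <- if (j <= length(matrix$parameters)) matrix$parameters[j] else "final_rank"
    lines <- c(lines, sprintf(
      '<text x="%d" y="%d" font-size="8" transform="rotate(-45 %d %d)">%s</text>',
      pad_left + (j - 1) * cell + 4, pad_top - 6,
      pad_left + (j - 1) * cell + 4, pad_top - 6, xml_escape(label)))
  }
  for (i in seq_len(n)) {
    y <- pad_top + (i - 1) * cell
    lines <- c(lines, sprintf(
      '<text x="4" y="%d" font-size="10">%s (%s)</text>',
      y + cell - 7, xml_escape(matrix$rows$name[i]), matrix$rows$phase[i]))
    for (j in seq_along(matrix$parameters)) {
      lines <- c(lines, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="white"/>',
        pad_left + (j - 1) * cell, y, cell, cell,
        TPP_COLORS[[matrix$cells[i, j]]]))
    }
    lines <- c(lines, sprintf(
      '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="white"/>',
      pad_left + length(matrix$parameters) * cell, y, cell, cell,
      TIER_COLORS[[matrix$rows$tier[i]]]))
  }
  ly <- pad_top + n * cell + 20
  for (k in seq_along(matrix_legend_lines())) {
    lines <- c(lines, sprintf('<text x="4" y="%d" font-size="9">%s</text>',
                              ly + 14 * k, xml_escape(matrix_legend_lines()[k])))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, useBytes = TRUE)
}

export_matrix_html <- function(matrix, path) {
  td <- function(color) sprintf('<td style="background:%s;width:22px">&nbsp;</td>', color)
  rows <- vapply(seq_len(nrow(matrix$cells)), function(i) {
    paste0("<tr><th>", xml_escape(matrix$rows$name[i]), " (",
           matrix$rows$phase[i], ")</th>",
           paste(vapply(matrix$cells[i, ], function(tok) td(TPP_COLORS[[tok]]),
                        character(1)), collapse = ""),
           td(TIER_COLORS[[matrix$rows$tier[i]]]), "</tr>")
  }, character(1))
  header <- paste0("<tr><th></th>",
                   paste(sprintf("<th>%s</th>", c(matrix$parameters, "final_rank")),
                         collapse = ""), "</tr>")
  writeLines(c("<!DOCTYPE html>", "<html><body>",
               "<table border='0' cellspacing='1'>", header, rows, "</table>",
               paste0("<p>", paste(matrix_legend_lines(), collapse = " "), "</p>"),
               "</body></html>"), path, useBytes = TRUE)
}
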