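# traffic_light: color mapping, matrix construction, exports

test_that("color_map follows the figure legends and is total/injective per scale", {
  expect_identical(color_map("efficacy", "met_preferred"), "dark_green")
  expect_identical(color_map("setting", "single_setting"), "yellow")
  expect_identical(color_map("eml_listing", "not_met"), "red")
  expect_identical(color_map("stability", "met"), "light_green")
  for (p in tpp_parameters()) {
    adm <- admissible_levels(p)
    colors <- color_map(rep(p, length(adm)), adm)
    expect_false(anyNA(colors))                 # total
    expect_identical(anyDuplicated(colors), 0L) # injective within the scale
    expect_identical(color_map(p, "unknown"), "grey")
  }
  expect_error(color_map("eml_listing", "met_minimum"), class = "tpp_value_error")
})

make_rank_fixture <- function(sheets, phases) {
  rows <- lapply(seq_along(sheets), function(i) {
    sc <- score_sheet(sheets[[i]])
    data.frame(candidate_id = sheets[[i]]$candidate_id,
               name = paste0("cand ", sheets[[i]]$candidate_id),
               phase = phases[[i]], weighted_score = sc$weighted_score,
               max_achievable = sc$max_achievable,
               score_fraction = sc$score_fraction,
               tier = rank_tier(sc$score_fraction, phases[[i]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("build_matrix maps cells and orders rows deterministically", {
  sheets <- list(floor_sheet(candidate_id = "a"),
                 uniform_sheet("met_preferred", candidate_id = "b"),
                 uniform_sheet("unknown", candidate_id = "c"))
  res <- make_rank_fixture(sheets, c("phase2", "phase2", "phase3"))
  m <- build_matrix(res, sheets)
  expect_identical(dim(m$cells), c(3L, 9L))
  # phase3 first, then phase2 by descending score
  expect_identical(m$rows$candidate_id, c("c", "b", "a"))
  # hand-drawn grids (row 1 = "c" all-unknown, row 2 = "b", row 3 = "a")
  expect_identical(unique(unname(m$cells[1, ])), "grey")  # all-unknown row
  expect_identical(unname(m$cells[2, ]),
                   unname(color_map(tpp_parameters(),
                                    rep("met_preferred", 9))))
  expect_identical(unname(m$cells[3, "stability"]), "red")
  # orphan sheet -> integrity error
  expect_error(build_matrix(res[-1, ], sheets), class = "tpp_integrity_error")
})

test_that("matrix CSV export round-trips the token grid", {
  set.seed(31)
  sheets <- lapply(1:4, function(i)
    random_sheet(candidate_id = paste0("c", i), rater_id = "consensus"))
  res <- make_rank_fixture(sheets, rep(c("phase1", "phase3"), 2))
  m <- build_matrix(res, sheets)
  path <- withr::local_tempfile(fileext = ".csv")
  export_matrix(m, path, format = "csv")
  back <- read_matrix_csv(path)
  expect_identical(back$cells, m$cells)
  expect_identical(back$rows, m$rows)
  # empty matrix -> header-only CSV
  m0 <- build_matrix(res[0, ], list())
  path0 <- withr::local_tempfile(fileext = ".csv")
  export_matrix(m0, path0)
  expect_length(readLines(path0), 1L)
  expect_identical(nrow(read_matrix_csv(path0)$cells), 0L)
})

test_that("SVG export emits one rect per cell incl. final rank", {
  set.seed(77)
  n <- 11L
  sheets <- lapply(seq_len(n), function(i)
    random_sheet(candidate_id = paste0("c", i), rater_id = "consensus"))
  res <- make_rank_fixture(sheets, rep(tpp_rankable_phases(), length.out = n))
  m <- build_matrix(res, sheets)
  path <- withr::local_tempfile(fileext = ".svg")
  export_matrix(m, path, format = "svg")
  svg <- paste(readLines(path), collapse = "\n")
  expect_identical(lengths(regmatches(svg, gregexpr("<rect ", svg))), n * 10L)
  expect_match(svg, "met preferred = dark green")
  # html export sanity
  ph <- withr::local_tempfile(fileext = ".html")
  export_matrix(m, ph, format = "html")
  html <- paste(readLines(ph), collapse = "\n")
  expect_identical(lengths(regmatches(html, gregexpr("<tr>", html))), n + 1L)
})
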