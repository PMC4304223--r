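# shared helpers: build tiny sheets in code and compare checker output with
# the fixture generator's bookkeeping

# sheet from a matrix-like list of rows; NA = empty cell, character = text
# (never sniffed), numbers/dates/logicals kept as-is
sheet_from_rows <- function(rows, name = "s") {
  sh <- new_sheet(name)
  for (r in seq_along(rows)) {
    row <- rows[[r]]
    for (cc in seq_along(row)) {
      v <- row[[cc]]
      if (length(v) == 1 && is.na(v) && !inherits(v, "Date")) next
      sh <- set_cell(sh, r, cc, v, as_text = is.character(v))
    }
  }
  sh
}

wb1 <- function(sh) new_workbook(list(sh))

# canonical (rule, sorted locations) signature of a report / of bookkeeping
issue_signature <- function(report) {
  sort(vapply(report$issues, function(is) {
    paste0(is$rule_id, "|", paste(sort(is$locations), collapse = ","))
  }, character(1)))
}

injection_signature <- function(wb) {
  inj <- fixture_injections(wb)
  sort(unname(vapply(names(inj), function(id) {
    paste0(id, "|", paste(sort(inj[[id]]$locations), collapse = ","))
  }, character(1))))
}

expect_injections_detected <- function(defects, seed = 1L) {
  wb <- generate_fixture(defects, seed = seed)
  report <- run_all_checks(wb)
  expect_identical(issue_signature(report), injection_signature(wb),
                   label = paste("defects:", paste(defects, collapse = "+")))
  invisible(report)
}

# workbook equality on the supported round-trip surface
expect_wb_equal <- function(got, want) {
  expect_identical(sheet_names(got), sheet_names(want))
  for (i in seq_along(want$sheets)) {
    g <- got$sheets[[i]]; w <- want$sheets[[i]]
    cols <- c("row", "col", "kind", "formula", "comment", "fill", "font_color")
    expect_identical(g$cells[cols], w$cells[cols],
                     label = paste("cells of sheet", w$name))
    expect_true(all(mapply(identical, g$cells$value, w$cells$value)),
                label = paste("cell values of sheet", w$name))
    expect_setequal(g$merged, w$merged)
    expect_identical(g$objects[order(g$objects$row, g$objects$col), ],
                     w$objects[order(w$objects$row, w$objects$col), ])
  }
}

# a fully populated metadata record touching all 42 file-level elements
full_metadata <- function() {
  ids <- file_level_ids()
  fl <- as.list(paste0("value of ", ids))
  names(fl) <- ids
  fl$today_date <- "2026-01-15"
  fl$temporal_begin <- "2011-08-01"
  fl$temporal_end <- "2011-08-08"
  fl$keywords <- c("limnology", "temperature", "survey")
  fl$creator_email <- "ana@example.org"
  fl$contact_email <- "lab@example.org"
  fl$west_bounding <- "-123.5"
  fl$east_bounding <- "-121.25"
  fl$north_bounding <- "38.2"
  fl$south_bounding <- "36.9"
  fl$identifier <- "ark:/99999/fk4x1"
  attributes <- data.frame(
    parameter_name = c("site", "sampledate", "temperature"),
    description = c("site code", "sampling date", "water temperature"),
    units = c("", "", "celsius"),
    measurement_type = c("nominal", "dateTime", "ratio"),
    missing_value_code = c("", "", "NA"),
    column_index = 1:3, stringsAsFactors = FALSE)
  new_metadata(fl, attributes)
}

# minimal complete record: the 7 required elements only
minimal_metadata <- function() {
  new_metadata(list(
    today_date = "2026-01-15", title = "Stream temperatures",
    abstract = "Hourly stream temperature at three sites.",
    keywords = "temperature", creator_first_name = "Ana",
    creator_last_name = "Mendez", creator_email = "ana@example.org"))
}
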