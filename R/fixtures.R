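#' Deterministic workbook fixture generator
#'
#' Builds a small field-survey-style workbook in memory: one table on sheet
#' `"data"` with a unique text header over typed columns (text site codes,
#' ISO dates, two numeric measurements) and eight data rows. With no
#' requested defects the fixture is pristine -- [run_all_checks()] reports
#' zero issues -- and each of the 11 rule ids can be injected as a defect at
#' recorded locations. Injections are constructed to be pairwise independent:
#' injecting one rule's defect never fires another rule. Two constructions
#' make that possible and are worth knowing about: the header defect is the
#' "two stacked header rows" variant (replacing header text with numbers
#' would make the text and date columns mixed-type), and the merged range is
#' placed over empty cells away from any table (a merge inside the table
#' would create interior blanks; a valued merge outside would create a second
#' region). The multiple-sheets defect adds a second sheet that is itself
#' pristine.
#'
#' Pseudo-randomness (fixed by `seed`) is used for filler data values only,
#' never for structure, so the same `(defects, seed)` pair always produces an
#' identical workbook.
#'
#' @param defects character vector of rule ids to inject (subset of
#'   [rule_ids()]); empty for the pristine fixture.
#' @param seed integer seed for filler values.
#' @return a `wb_workbook` whose `"injections"` attribute (see
#'   [fixture_injections()]) maps each injected rule id to its expected
#'   issue locations.
#' @examples
#' wb <- generate_fixture(c("merged_cells"))
#' fixture_injections(wb)$merged_cells
#' @export
generate_fixture <- function(defects = character(), seed = 1L) {
  unknown <- setdiff(defects, rule_ids())
  if (length(unknown) > 0) {
    stop("unknown defect id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(seed)

  n <- 8L
  hr <- if ("header_problem" %in% defects) 2L else 1L
  inj <- list()

  sh <- new_sheet("data")
  header <- c("site", "sampledate", "temperature", "abundance")
  for (j in seq_along(header)) sh <- set_cell(sh, 1L, j, header[j])
  if (hr == 2L) {
    units_row <- c("id", "day", "degrees", "n")
    for (j in seq_along(units_row)) sh <- set_cell(sh, 2L, j, units_row[j])
    inj$header_problem <- list(sheet = "data", locations = "A1:D2")
  }
  sites <- sprintf("site_%02d", seq_len(n))
  dates <- as.Date("2011-08-01") + seq_len(n) - 1L
  temps <- round(stats::runif(n, 4, 28), 1)
  counts <- as.numeric(sample.int(500L, n))
  for (i in seq_len(n)) {
    r <- hr + i
    sh <- set_cell(sh, r, 1L, sites[i])
    sh <- set_cell(sh, r, 2L, dates[i])
    sh <- set_cell(sh, r, 3L, temps[i])
    sh <- set_cell(sh, r, 4L, counts[i])
  }
  bottom <- hr + n

  if ("embedded_objects" %in% defects) {
    sh <- add_object(sh, "chart", 2L, 6L)
    inj$embedded_objects <- list(sheet = "data", locations = "F2")
  }
  if ("embedded_comments" %in% defects) {
    sh <- set_cell(sh, hr + 2L, 2L, comment = "instrument recalibrated")
    sh <- set_cell(sh, hr + 4L, 4L, comment = "approximate count")
    inj$embedded_comments <- list(
      sheet = "data", locations = c(a1(hr + 2L, 2L), a1(hr + 4L, 4L)))
  }
  if ("commas" %in% defects) {
    sh <- set_cell(sh, hr + 2L, 1L, "Oakland, CA")
    inj$commas <- list(sheet = "data", locations = a1(hr + 2L, 1L))
  }
  if ("special_characters" %in% defects) {
    sh <- set_cell(sh, hr + 5L, 1L, "\u00b5g/L")
    inj$special_characters <- list(sheet = "data", locations = a1(hr + 5L, 1L))
  }
  if ("color_coding" %in% defects) {
    sh <- set_cell(sh, hr + 1L, 3L, fill = "FFFF00")
    sh <- set_cell(sh, hr + 3L, 3L, font_color = "FF0000")
    inj$color_coding <- list(
      sheet = "data", locations = c(a1(hr + 1L, 3L), a1(hr + 3L, 3L)))
  }
  if ("mixed_types" %in% defects) {
    sh <- set_cell(sh, hr + 6L, 4L, "n/a", as_text = TRUE)
    inj$mixed_types <- list(
      sheet = "data", locations = range_ref(hr + 1L, 4L, bottom, 4L))
  }
  if ("non_contiguous" %in% defects) {
    sh <- set_cell(sh, 1L, 6L, "plot")
    sh <- set_cell(sh, 1L, 7L, "area")
    for (i in 1:3) {
      sh <- set_cell(sh, 1L + i, 6L, as.numeric(i))
      sh <- set_cell(sh, 1L + i, 7L, round(stats::runif(1, 10, 90), 1))
    }
    inj$non_contiguous <- list(
      sheet = "data",
      locations = c(range_ref(1L, 1L, bottom, 4L), "F1:G4"))
  }
  if ("merged_cells" %in% defects) {
    sh <- merge_cells(sh, "F6:G7")
    inj$merged_cells <- list(sheet = "data", locations = "F6:G7")
  }
  if ("blank_cells" %in% defects) {
    sh <- clear_cell(sh, hr + 4L, 3L)
    inj$blank_cells <- list(sheet = "data", locations = a1(hr + 4L, 3L))
  }

  sheets <- list(sh)
  if ("multiple_sheets" %in% defects) {
    sh2 <- new_sheet("notes")
    sh2 <- set_cell(sh2, 1L, 1L, "observer")
    sh2 <- set_cell(sh2, 1L, 2L, "visits")
    sh2 <- set_cell(sh2, 2L, 1L, "AM")
    sh2 <- set_cell(sh2, 2L, 2L, 3)
    sh2 <- set_cell(sh2, 3L, 1L, "RD")
    sh2 <- set_cell(sh2, 3L, 2L, 5)
    sheets <- c(sheets, list(sh2))
    inj$multiple_sheets <- list(sheet = "data", locations = c("data", "notes"))
  }

  wb <- new_workbook(
    sheets,
    doc_properties = list(author = "Ana Mendez", title = "field_samples"),
    source_format = NA_character_)
  attr(wb, "injections") <- inj
  wb
}

#' @rdname generate_fixture
#' @param wb a fixture workbook.
#' @export
fixture_injections <- function(wb) attr(wb, "injections") %||% list()
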