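# The 11 best-practices checks.
#
# Scoping follows the remedies' own framing: rules that talk about cells in a
# data table (commas, special characters, color coding, mixed types, blank
# cells) are evaluated inside detected table regions only, so decorative
# content outside tables does not flood reports; rules about workbook-level
# features (embedded objects, comments, merged cells, multiple sheets) are
# global. Each check returns a list of issues, aggregated per (rule, sheet)
# so a large file yields one located issue per sheet rather than thousands.

cells_in_region <- function(sheet, region, exclude_header = FALSE) {
  b <- region$bounds
  top <- b$top
  if (exclude_header) top <- top + region$header_row_count
  cells <- sheet$cells
  cells[cells$row >= top & cells$row <= b$bottom &
        cells$col >= b$left & cells$col <= b$right, , drop = FALSE]
}

region_ref <- function(region) {
  b <- region$bounds
  range_ref(b$top, b$left, b$bottom, b$right)
}

#' Individual best-practice checks
#'
#' Each `check_*()` function evaluates one rule of [rule_catalogue()] against
#' a workbook and returns a list of issues (possibly empty). `regions` is the
#' per-sheet region list from [detect_regions()], computed once by
#' [run_all_checks()] and shared across the region-scoped rules.
#'
#' @param wb a `wb_workbook`.
#' @param regions named list (by sheet) of lists of `table_region`s.
#' @return a list of issues; each issue has `rule_id`, `sheet`, `locations`
#'   (A1 cells or ranges; sheet names for the multiple-sheets rule), the
#'   catalogue `why`/`remedy` texts, `auto_fixable`, `severity` and `detail`.
#' @name checks
NULL

#' @rdname checks
#' @export
check_embedded_objects <- function(wb, regions = NULL) {
  out <- list()
  for (sh in wb$sheets) {
    if (nrow(sh$objects) == 0) next
    locs <- a1(sh$objects$row, sh$objects$col)
    out <- c(out, list(new_issue("embedded_objects", sh$name, locs,
                                 detail = paste(sh$objects$kind, collapse = ", "))))
  }
  out
}

#' @rdname checks
#' @export
check_embedded_comments <- function(wb, regions = NULL) {
  out <- list()
  for (sh in wb$sheets) {
    commented <- sh$cells[!is.na(sh$cells$comment), , drop = FALSE]
    if (nrow(commented) == 0) next
    out <- c(out, list(new_issue("embedded_comments", sh$name,
                                 a1(commented$row, commented$col))))
  }
  out
}

#' @rdname checks
#' @export
check_commas <- function(wb, regions = workbook_regions(wb)) {
  out <- list()
  for (sh in wb$sheets) {
    locs <- character()
    for (region in regions[[sh$name]]) {
      cells <- cells_in_region(sh, region)
      hit <- cells$kind == "text" &
        grepl(",", vapply(cells$value, as.character, character(1)), fixed = TRUE)
      locs <- c(locs, a1(cells$row[hit], cells$col[hit]))
    }
    if (length(locs) > 0) {
      out <- c(out, list(new_issue("commas", sh$name, locs)))
    }
  }
  out
}

#' @rdname checks
#' @export
check_special_characters <- function(wb, regions = workbook_regions(wb)) {
  out <- list()
  for (sh in wb$sheets) {
    locs <- character()
    for (region in regions[[sh$name]]) {
      cells <- cells_in_region(sh, region)
      txt <- vapply(cells$value, as.character, character(1))
      # commas are rule 3's concern: remove them before testing membership
      hit <- cells$kind == "text" &
        !grepl(SPECIAL_ALLOWED_PATTERN, gsub(",", "", txt, fixed = TRUE))
      locs <- c(locs, a1(cells$row[hit], cells$col[hit]))
    }
    if (length(locs) > 0) {
      out <- c(out, list(new_issue("special_characters", sh$name, locs)))
    }
  }
  out
}

#' @rdname checks
#' @export
check_color_coding <- function(wb, regions = workbook_regions(wb)) {
  out <- list()
  for (sh in wb$sheets) {
    locs <- character()
    for (region in regions[[sh$name]]) {
      cells <- cells_in_region(sh, region)
      hit <- !is.na(cells$fill) | !is.na(cells$font_color)
      locs <- c(locs, a1(cells$row[hit], cells$col[hit]))
    }
    if (length(locs) > 0) {
      out <- c(out, list(new_issue("color_coding", sh$name, locs)))
    }
  }
  out
}

#' @rdname checks
#' @export
check_mixed_types <- function(wb, regions = workbook_regions(wb)) {
  out <- list()
  for (sh in wb$sheets) {
    locs <- character(); details <- character()
    for (region in regions[[sh$name]]) {
      b <- region$bounds
      body_top <- b$top + region$header_row_count
      if (body_top > b$bottom) next
      for (cc in b$left:b$right) {
        cells <- sh$cells[sh$cells$col == cc & sh$cells$row >= body_top &
                          sh$cells$row <= b$bottom, , drop = FALSE]
        kinds <- unique(cells$kind[cells$kind %in%
                                   c("number", "text", "date", "boolean")])
        if (length(kinds) >= 2) {
          locs <- c(locs, range_ref(body_top, cc, b$bottom, cc))
          details <- c(details, paste(sort(kinds), collapse = "+"))
        }
      }
    }
    if (length(locs) > 0) {
      out <- c(out, list(new_issue("mixed_types", sh$name, locs,
                                   detail = paste(details, collapse = "; "))))
    }
  }
  out
}

#' @rdname checks
#' @export
check_non_contiguous <- function(wb, regions = workbook_regions(wb)) {
  out <- list()
  for (sh in wb$sheets) {
    rs <- regions[[sh$name]]
    if (length(rs) >= 2) {
      out <- c(out, list(new_issue("non_contiguous", sh$name,
                                   vapply(rs, region_ref, character(1)))))
    }
  }
  out
}

#' @rdname checks
#' @export
check_merged_cells <- function(wb, regions = NULL) {
  out <- list()
  for (sh in wb$sheets) {
    if (length(sh$merged) > 0) {
      out <- c(out, list(new_issue("merged_cells", sh$name, sh$merged)))
    }
  }
  out
}

#' @rdname checks
#' @export
check_blank_cells <- function(wb, regions = workbook_regions(wb)) {
  out <- list()
  for (sh in wb$sheets) {
    locs <- character()
    for (region in regions[[sh$name]]) {
      b <- region$bounds
      valued <- sheet_value_matrix(sh, b)
      blanks <- which(!valued, arr.ind = TRUE)
      if (nrow(blanks) > 0) {
        locs <- c(locs, a1(blanks[, 1] + b$top - 1L, blanks[, 2] + b$left - 1L))
      }
    }
    if (length(locs) > 0) {
      out <- c(out, list(new_issue("blank_cells", sh$name, sort(locs))))
    }
  }
  out
}

# logical occupancy matrix of a bounds rectangle (TRUE = holds a value)
sheet_value_matrix <- function(sh, b) {
  m <- matrix(FALSE, nrow = b$bottom - b$top + 1L, ncol = b$right - b$left + 1L)
  cells <- sh$cells[sh$cells$kind != "empty", , drop = FALSE]
  inb <- cells$row >= b$top & cells$row <= b$bottom &
         cells$col >= b$left & cells$col <= b$right
  m[cbind(cells$row[inb] - b$top + 1L, cells$col[inb] - b$left + 1L)] <- TRUE
  m
}

#' @rdname checks
#' @export
check_header <- function(wb, regions = workbook_regions(wb)) {
  out <- list()
  for (sh in wb$sheets) {
    locs <- character(); details <- character()
    for (region in regions[[sh$name]]) {
      b <- region$bounds
      if (region$header_row_count >= 2) {
        locs <- c(locs, range_ref(b$top, b$left,
                                  b$top + region$header_row_count - 1L, b$right))
        details <- c(details, "multiple")
      } else if (region$header_row_count == 0) {
        top_row <- sh$cells[sh$cells$row == b$top & sh$cells$col >= b$left &
                            sh$cells$col <= b$right, , drop = FALSE]
        full_text_row <- nrow(top_row) == (b$right - b$left + 1L) &&
          all(top_row$kind == "text")
        dup <- full_text_row && anyDuplicated(
          vapply(top_row$value, as.character, character(1))) > 0
        locs <- c(locs, range_ref(b$top, b$left, b$top, b$right))
        details <- c(details, if (dup) "duplicate" else "absent")
      }
    }
    if (length(locs) > 0) {
      out <- c(out, list(new_issue("header_problem", sh$name, locs,
                                   detail = paste(details, collapse = "; "))))
    }
  }
  out
}

#' @rdname checks
#' @export
check_multiple_sheets <- function(wb, regions = NULL) {
  nonempty <- Filter(sheet_nonempty, wb$sheets)
  if (length(nonempty) <= 1) return(list())
  nms <- vapply(nonempty, `[[`, character(1), "name")
  list(new_issue("multiple_sheets", nms[1], nms))
}

#' Run all 11 best-practice checks
#'
#' Evaluates the full rule catalogue against a workbook, in catalogue order,
#' and assembles a check report. The report is deterministic for a fixed
#' workbook (up to its timestamp): `passed` is `TRUE` exactly when no rule
#' fired, and `per_rule_counts` holds the number of issues per rule for all
#' 11 rule ids.
#'
#' @param wb a `wb_workbook`.
#' @param source label recorded in the report (defaults to the workbook's
#'   source path).
#' @return a `check_report`: `source`, `checked_at`, `issues`,
#'   `per_rule_counts`, `passed`.
#' @examples
#' wb <- generate_fixture()  # pristine
#' run_all_checks(wb)$passed
#' @export
run_all_checks <- function(wb, source = wb$source_path) {
  regions <- workbook_regions(wb)
  checkers <- list(
    embedded_objects = check_embedded_objects,
    embedded_comments = check_embedded_comments,
    commas = check_commas,
    special_characters = check_special_characters,
    color_coding = check_color_coding,
    mixed_types = check_mixed_types,
    non_contiguous = check_non_contiguous,
    merged_cells = check_merged_cells,
    blank_cells = check_blank_cells,
    header_problem = check_header,
    multiple_sheets = check_multiple_sheets)
  stopifnot(identical(names(checkers), rule_ids()))
  issues <- do.call(c, lapply(checkers, function(f) f(wb, regions)))
  issues <- unname(issues)
  counts <- table(factor(vapply(issues, `[[`, character(1), "rule_id"),
                         levels = rule_ids()))
  structure(
    list(source = if (is.null(source) || is.na(source)) "<in-memory>" else source,
         checked_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         issues = issues,
         per_rule_counts = stats::setNames(as.integer(counts), rule_ids()),
         passed = length(issues) == 0),
    class = "check_report")
}

#' @export
print.check_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
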