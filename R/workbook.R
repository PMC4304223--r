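#' In-memory workbook model
#'
#' A neutral, format-agnostic model of spreadsheet content. A workbook is an
#' ordered list of sheets; a sheet is a sparse collection of cells plus merged
#' ranges and anchors of embedded objects (charts, pictures, pivot tables). A
#' cell carries its raw value, a value kind (see [value_kind_of()]), and
#' optionally a formula string, a comment, a fill color and a font color.
#' Colors are normalized 6-digit hex RGB strings (e.g. `"FFFF00"`); absence of
#' explicit formatting is `NA`, never a hex value, so "has non-default
#' formatting" is a crisp predicate. All model operations are functional: they
#' return a modified copy and never mutate their input.
#'
#' @param name sheet name.
#' @param sheets list of sheets created by [new_sheet()].
#' @param doc_properties named list of document properties (`author`, `title`,
#'   `created`).
#' @param source_path,source_format provenance of a workbook read from disk.
#' @return `new_workbook()` a `wb_workbook`; `new_sheet()` a `wb_sheet`.
#' @examples
#' sh <- new_sheet("Data")
#' sh <- set_cell(sh, 1, 1, "site")
#' sh <- set_cell(sh, 2, 1, 41.2)
#' wb <- new_workbook(list(sh))
#' used_range(wb$sheets[[1]])
#' @name workbook-model
NULL

empty_cells_df <- function() {
  data.frame(
    row = integer(), col = integer(), kind = character(),
    formula = character(), comment = character(),
    fill = character(), font_color = character(),
    stringsAsFactors = FALSE
  ) |> (\(d) { d$value <- list(); d })()
}

#' @rdname workbook-model
#' @export
new_sheet <- function(name) {
  stopifnot(is.character(name), nzchar(name))
  structure(
    list(
      name = name,
      cells = empty_cells_df(),
      merged = character(),
      objects = data.frame(kind = character(), row = integer(),
                           col = integer(), stringsAsFactors = FALSE)
    ),
    class = "wb_sheet"
  )
}

#' @rdname workbook-model
#' @export
new_workbook <- function(sheets = list(), doc_properties = list(),
                         source_path = NA_character_,
                         source_format = NA_character_) {
  nm <- vapply(sheets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("sheet names must be unique", call. = FALSE)
  structure(
    list(sheets = sheets, doc_properties = doc_properties,
         source_path = source_path, source_format = source_format),
    class = "wb_workbook"
  )
}

#' Set, get or clear a cell
#'
#' `set_cell()` writes a value and/or annotations at `(row, col)`; fields left
#' `NULL` keep their previous content. The value kind is derived with
#' [value_kind_of()] unless a character value should stay literal text
#' (`as_text = TRUE`), which is how spreadsheet text cells that merely look
#' numeric are represented.
#'
#' @param sheet a `wb_sheet`.
#' @param row,col 1-based cell coordinates.
#' @param value cell value (number, text, `Date`, logical) or `NA` to blank
#'   the value while keeping annotations.
#' @param formula,comment,comment_text,fill,font_color optional annotations;
#'   `NA` clears.
#' @param as_text force a character value to kind `"text"` without sniffing.
#' @return `set_cell()`/`clear_cell()` the modified sheet; `get_cell()` a list
#'   (`value`, `kind`, `formula`, `comment`, `fill`, `font_color`) or `NULL`
#'   for a cell that carries nothing.
#' @export
set_cell <- function(sheet, row, col, value = NULL, formula = NULL,
                     comment = NULL, fill = NULL, font_color = NULL,
                     as_text = FALSE) {
  stopifnot(inherits(sheet, "wb_sheet"), row >= 1, col >= 1)
  cells <- sheet$cells
  i <- which(cells$row == row & cells$col == col)
  if (length(i) == 0) {
    new <- data.frame(row = as.integer(row), col = as.integer(col),
                      kind = "empty", formula = NA_character_,
                      comment = NA_character_, fill = NA_character_,
                      font_color = NA_character_, stringsAsFactors = FALSE)
    new$value <- list(NA)
    cells <- rbind(cells, new)
    i <- nrow(cells)
  }
  if (!is.null(value)) {
    if (is.character(value) && as_text) {
      cells$value[[i]] <- value
      cells$kind[i] <- if (is.na(value) || !nzchar(value)) "empty" else "text"
    } else {
      cells$value[[i]] <- value
      cells$kind[i] <- value_kind_of(value)
    }
  }
  if (!is.null(formula)) cells$formula[i] <- formula
  if (!is.null(comment)) cells$comment[i] <- comment
  if (!is.null(fill)) cells$fill[i] <- norm_color(fill)
  if (!is.null(font_color)) cells$font_color[i] <- norm_color(font_color)
  # drop rows that carry nothing at all
  if (cells$kind[i] == "empty" && all(is.na(unlist(
    cells[i, c("formula", "comment", "fill", "font_color")])))) {
    cells <- cells[-i, , drop = FALSE]
  }
  sheet$cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(sheet$cells) <- NULL
  sheet
}

#' @rdname set_cell
#' @export
get_cell <- function(sheet, row, col) {
  i <- which(sheet$cells$row == row & sheet$cells$col == col)
  if (length(i) == 0) return(NULL)
  c(list(value = sheet$cells$value[[i]]),
    as.list(sheet$cells[i, c("kind", "formula", "comment", "fill",
                             "font_color")]))
}

#' @rdname set_cell
#' @export
clear_cell <- function(sheet, row, col) {
  keep <- !(sheet$cells$row == row & sheet$cells$col == col)
  sheet$cells <- sheet$cells[keep, , drop = FALSE]
  rownames(sheet$cells) <- NULL
  sheet
}

norm_color <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NA_character_)
  x <- toupper(sub("^#", "", x))
  if (nchar(x) == 8) x <- substring(x, 3)  # drop alpha channel
  if (!grepl("^[0-9A-F]{6}$", x)) stop("not a hex RGB color: ", x, call. = FALSE)
  x
}

#' Merge a rectangular cell range
#'
#' @param sheet a `wb_sheet`.
#' @param ref an A1 range such as `"B2:C3"`.
#' @return the modified sheet.
#' @export
merge_cells <- function(sheet, ref) {
  r <- parse_range(ref)
  for (m in sheet$merged) {
    o <- parse_range(m)
    if (r$top <= o$bottom && o$top <= r$bottom &&
        r$left <= o$right && o$left <= r$right) {
      stop("merged ranges overlap: ", ref, " vs ", m, call. = FALSE)
    }
  }
  sheet$merged <- c(sheet$merged, range_ref(r$top, r$left, r$bottom, r$right))
  sheet
}

#' Record an embedded object anchor
#'
#' Embedded charts, pictures and pivot tables are modeled as presence plus an
#' anchor cell only; their content is out of scope for a CSV-compatibility
#' linter.
#'
#' @param sheet a `wb_sheet`.
#' @param kind `"chart"`, `"picture"` or `"pivot_table"`.
#' @param row,col anchor cell.
#' @return the modified sheet.
#' @export
add_object <- function(sheet, kind, row, col) {
  kind <- match.arg(kind, c("chart", "picture", "pivot_table"))
  sheet$objects <- rbind(
    sheet$objects,
    data.frame(kind = kind, row = as.integer(row), col = as.integer(col),
               stringsAsFactors = FALSE)
  )
  sheet
}

#' Minimal bounding rectangle of a sheet's non-empty cells
#'
#' @param sheet a `wb_sheet`.
#' @param values_only count only cells holding a value (default); otherwise
#'   any cell carrying an annotation extends the range.
#' @return a list (`top`, `left`, `bottom`, `right`) or `NULL` for a sheet
#'   with no qualifying cells.
#' @export
used_range <- function(sheet, values_only = TRUE) {
  cells <- sheet$cells
  if (values_only) cells <- cells[cells$kind != "empty", , drop = FALSE]
  if (nrow(cells) == 0) return(NULL)
  list(top = min(cells$row), left = min(cells$col),
       bottom = max(cells$row), right = max(cells$col))
}

#' @rdname workbook-model
#' @export
sheet_names <- function(wb) vapply(wb$sheets, `[[`, character(1), "name")

sheet_by_name <- function(wb, name) {
  i <- match(name, sheet_names(wb))
  if (is.na(i)) stop("no sheet named '", name, "'", call. = FALSE)
  wb$sheets[[i]]
}

#' Add or replace a sheet (matched by name)
#'
#' @param wb a `wb_workbook`.
#' @param sheet a `wb_sheet`.
#' @return the modified workbook.
#' @export
add_sheet <- function(wb, sheet) {
  i <- match(sheet$name, sheet_names(wb))
  if (is.na(i)) wb$sheets <- c(wb$sheets, list(sheet))
  else wb$sheets[[i]] <- sheet
  wb
}

# a sheet is "non-empty" when it holds at least one value
sheet_nonempty <- function(sheet) any(sheet$cells$kind != "empty")

#' @export
print.wb_workbook <- function(x, ...) {
  cat("<workbook>", length(x$sheets), "sheet(s)\n")
  for (sh in x$sheets) {
    ur <- used_range(sh)
    cat(sprintf("  %s: %d cell(s)%s%s%s\n", sh$name, nrow(sh$cells),
                if (is.null(ur)) "" else paste0(
                  ", used ", range_ref(ur$top, ur$left, ur$bottom, ur$right)),
                if (length(sh$merged)) paste0(
                  ", merged ", paste(sh$merged, collapse = " ")) else "",
                if (nrow(sh$objects)) paste0(
                  ", ", nrow(sh$objects), " embedded object(s)") else ""))
  }
  invisible(x)
}
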