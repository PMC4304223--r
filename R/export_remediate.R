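#' Export a workbook as archive-ready CSV
#'
#' Writes one RFC 4180 CSV per non-empty sheet: a multi-sheet workbook is
#' split because CSV cannot hold more than one table. Files are named
#' `<stem>_<sheet>.csv` (just `<stem>.csv` for a single sheet), with sheet
#' names sanitized for filesystems (`[^A-Za-z0-9_-]` becomes `_`, collisions
#' suffixed `_2`, `_3`, ...). Cells are serialized to survive re-reading:
#' numbers as shortest round-trip decimals, dates as ISO 8601, text quoted
#' when it contains a comma, quote or newline. Comments, colors, merges and
#' embedded objects are dropped -- that is what the best-practices checks
#' warn about -- with merged ranges contributing their anchor value at the
#' top-left position and empty cells elsewhere. Output is UTF-8 without BOM;
#' the line terminator defaults to LF.
#'
#' @param wb a `wb_workbook`.
#' @param out_dir output directory (created if needed).
#' @param stem file-name stem; defaults to the workbook's source file stem
#'   or `"workbook"`.
#' @param line_ending `"lf"` (default) or `"crlf"`.
#' @return character vector of written file paths.
#' @export
export_csv <- function(wb, out_dir, stem = NULL,
                       line_ending = c("lf", "crlf")) {
  line_ending <- match.arg(line_ending)
  nonempty <- Filter(sheet_nonempty, wb$sheets)
  if (length(nonempty) == 0) {
    stop("nothing to export: workbook has no non-empty sheets", call. = FALSE)
  }
  if (is.null(stem)) {
    stem <- if (!is.na(wb$source_path)) {
      sub("\\.[^.]*$", "", basename(wb$source_path))
    } else "workbook"
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  names <- vapply(nonempty, `[[`, character(1), "name")
  safe <- gsub("[^A-Za-z0-9_-]", "_", names)
  for (i in seq_along(safe)) {
    n_before <- sum(safe[seq_len(i - 1)] == safe[i])
    if (n_before > 0) safe[i] <- paste0(safe[i], "_", n_before + 1)
  }
  files <- if (length(nonempty) == 1) {
    file.path(out_dir, paste0(stem, ".csv"))
  } else {
    file.path(out_dir, paste0(stem, "_", safe, ".csv"))
  }
  eol <- if (line_ending == "lf") "\n" else "\r\n"
  for (i in seq_along(nonempty)) {
    lines <- sheet_to_csv_lines(nonempty[[i]])
    con <- file(files[i], open = "wb")
    writeLines(lines, con, sep = eol, useBytes = TRUE)
    close(con)
  }
  files
}

csv_field <- function(value, kind) {
  s <- switch(kind,
    empty = "",
    number = num_to_str(value),
    date = format(value, "%Y-%m-%d"),
    boolean = if (isTRUE(value)) "TRUE" else "FALSE",
    as.character(value))
  if (grepl("[\",\n\r]", s)) {
    s <- paste0("\"", gsub("\"", "\"\"", s), "\"")
  }
  s
}

sheet_to_csv_lines <- function(sh) {
  ur <- used_range(sh)
  cells <- sh$cells[sh$cells$kind != "empty", , drop = FALSE]
  grid <- matrix("", nrow = ur$bottom, ncol = ur$right)
  for (i in seq_len(nrow(cells))) {
    grid[cells$row[i], cells$col[i]] <-
      csv_field(cells$value[[i]], cells$kind[i])
  }
  enc2utf8(apply(grid, 1, paste, collapse = ","))
}

#' Bulk remediation transforms
#'
#' Each transform implements one of the catalogue's auto-fixable remedies and
#' returns a new workbook; inputs are never mutated, and every transform is
#' idempotent. After applying all four, the embedded-objects,
#' embedded-comments, color-coding and merged-cells rules report zero issues.
#'
#' * `comments_to_column()`: for each detected table region containing
#'   commented cells, appends a rightmost column headed `"Comments"` holding,
#'   per row, that row's comment texts concatenated in column order with
#'   `"; "`; then removes all comments. Comments attached to cells outside
#'   any table region are removed without relocation.
#' * `strip_formatting()`: clears all fill and font colors.
#' * `strip_objects()`: removes all embedded-object anchors.
#' * `unmerge_fill()`: dissolves each merged range, replicating the anchor
#'   (top-left) value into every cell of the former range so no information
#'   is lost -- the information-preserving variant of "un-merge and annotate".
#'
#' @param wb a `wb_workbook`.
#' @return a new `wb_workbook`.
#' @name remediation
NULL

#' @rdname remediation
#' @export
comments_to_column <- function(wb) {
  for (k in seq_along(wb$sheets)) {
    sh <- wb$sheets[[k]]
    if (!any(!is.na(sh$cells$comment))) next
    for (region in detect_regions(sh)) {
      b <- region$bounds
      commented <- sh$cells[!is.na(sh$cells$comment) &
                            sh$cells$row >= b$top & sh$cells$row <= b$bottom &
                            sh$cells$col >= b$left & sh$cells$col <= b$right, ,
                            drop = FALSE]
      if (nrow(commented) == 0) next
      new_col <- b$right + 1L
      if (region$header_row_count >= 1) {
        sh <- set_cell(sh, b$top, new_col, "Comments")
      }
      body_top <- b$top + region$header_row_count
      for (r in body_top:b$bottom) {
        in_row <- commented[commented$row == r, , drop = FALSE]
        if (nrow(in_row) == 0) next
        txt <- paste(in_row$comment[order(in_row$col)], collapse = "; ")
        sh <- set_cell(sh, r, new_col, txt, as_text = TRUE)
      }
    }
    sh$cells$comment <- NA_character_
    # cells that carried only a comment now carry nothing
    keep <- sh$cells$kind != "empty" | !is.na(sh$cells$formula) |
      !is.na(sh$cells$fill) | !is.na(sh$cells$font_color)
    sh$cells <- sh$cells[keep, , drop = FALSE]
    rownames(sh$cells) <- NULL
    wb$sheets[[k]] <- sh
  }
  wb
}

#' @rdname remediation
#' @export
strip_formatting <- function(wb) {
  for (k in seq_along(wb$sheets)) {
    sh <- wb$sheets[[k]]
    sh$cells$fill <- NA_character_
    sh$cells$font_color <- NA_character_
    keep <- sh$cells$kind != "empty" | !is.na(sh$cells$formula) |
      !is.na(sh$cells$comment)
    sh$cells <- sh$cells[keep, , drop = FALSE]
    rownames(sh$cells) <- NULL
    wb$sheets[[k]] <- sh
  }
  wb
}

#' @rdname remediation
#' @export
strip_objects <- function(wb) {
  for (k in seq_along(wb$sheets)) {
    wb$sheets[[k]]$objects <- wb$sheets[[k]]$objects[0, , drop = FALSE]
  }
  wb
}

#' @rdname remediation
#' @export
unmerge_fill <- function(wb) {
  for (k in seq_along(wb$sheets)) {
    sh <- wb$sheets[[k]]
    merged <- sh$merged
    sh$merged <- character()
    for (ref in merged) {
      b <- parse_range(ref)
      anchor <- get_cell(sh, b$top, b$left)
      if (is.null(anchor) || anchor$kind == "empty") next
      for (r in b$top:b$bottom) for (cc in b$left:b$right) {
        sh <- set_cell(sh, r, cc, anchor$value,
                       as_text = anchor$kind == "text")
      }
    }
    wb$sheets[[k]] <- sh
  }
  wb
}

#' @rdname remediation
#' @export
remediate_all <- function(wb) {
  strip_objects(strip_formatting(unmerge_fill(comments_to_column(wb))))
}
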