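#' Detect contiguous table regions on a sheet
#'
#' Spreadsheet users separate multiple tables on one tab with fully empty
#' rows or columns. `detect_regions()` recovers those tables: starting from
#' the sheet's used range, it recursively splits the current block at rows
#' and then columns that are entirely empty within the block, trims each
#' resulting block to the bounding rectangle of its non-empty cells, and
#' returns the maximal blocks in top-left reading order. The non-empty cells
#' of a sheet are partitioned exactly: every valued cell belongs to one and
#' only one region, and regions are pairwise disjoint. The procedure is a
#' reconstruction -- the splitting heuristic is this package's, chosen to
#' match the framing of empty rows/columns as table separators.
#'
#' @param sheet a `wb_sheet`.
#' @return a list of `table_region` objects, each with `sheet_name`, `bounds`
#'   (`top`, `left`, `bottom`, `right`, 1-based inclusive), `header_row`
#'   (absolute row index or `NA`) and `header_row_count`. Empty sheet: empty
#'   list.
#' @examples
#' sh <- new_sheet("s")
#' for (c in 1:3) sh <- set_cell(sh, 1, c, paste0("v", c))
#' for (r in 2:4) for (c in 1:3) sh <- set_cell(sh, r, c, r * c)
#' detect_regions(sh)[[1]]$bounds
#' @export
detect_regions <- function(sheet) {
  cells <- sheet$cells[sheet$cells$kind != "empty", , drop = FALSE]
  if (nrow(cells) == 0) return(list())
  occupied <- cells[, c("row", "col")]
  blocks <- split_block(occupied,
                        min(occupied$row), min(occupied$col),
                        max(occupied$row), max(occupied$col))
  blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "top"),
                         vapply(blocks, `[[`, numeric(1), "left"))]
  lapply(blocks, function(b) {
    region <- structure(
      list(sheet_name = sheet$name, bounds = b,
           header_row = NA_integer_, header_row_count = 0L),
      class = "table_region")
    hd <- detect_header(region, sheet)
    region$header_row <- hd$header_row
    region$header_row_count <- hd$header_row_count
    region
  })
}

# recursive empty-row / empty-column splitting; occ is a data.frame(row, col)
split_block <- function(occ, top, left, bottom, right) {
  inb <- occ[occ$row >= top & occ$row <= bottom &
             occ$col >= left & occ$col <= right, , drop = FALSE]
  if (nrow(inb) == 0) return(list())
  # trim to bounding box
  top <- min(inb$row); bottom <- max(inb$row)
  left <- min(inb$col); right <- max(inb$col)
  occ_rows <- sort(unique(inb$row))
  gaps <- setdiff(top:bottom, occ_rows)
  if (length(gaps) > 0) {
    bands <- consecutive_runs(occ_rows)
    return(do.call(c, lapply(bands, function(b)
      split_block(inb, b[1], left, b[2], right))))
  }
  occ_cols <- sort(unique(inb$col))
  gaps <- setdiff(left:right, occ_cols)
  if (length(gaps) > 0) {
    bands <- consecutive_runs(occ_cols)
    return(do.call(c, lapply(bands, function(b) {
      # a column split can expose new empty rows inside the sub-block
      split_block(inb, top, b[1], bottom, b[2])
    })))
  }
  list(list(top = top, left = left, bottom = bottom, right = right))
}

# split a sorted integer vector into runs of consecutive values;
# returns list of c(first, last)
consecutive_runs <- function(x) {
  breaks <- which(diff(x) > 1)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(x))
  lapply(seq_along(starts), function(i) c(x[starts[i]], x[ends[i]]))
}

#' Identify a region's header row(s)
#'
#' The top row of a region qualifies as a header when all of its cells are
#' text, none are empty across the region's width, and its values are unique
#' (case-sensitive exact match). Additional consecutive all-text, fully
#' populated rows are absorbed into a multi-row header only while at least
#' half of the region's columns still hold a non-text value somewhere below
#' the rows counted so far -- so a table whose body is entirely text keeps a
#' single-row header rather than swallowing its own data.
#'
#' @param region a `table_region` from [detect_regions()].
#' @param sheet the `wb_sheet` the region was detected on.
#' @return a list with `header_row` (absolute index of the top row, or `NA`
#'   when no header is detected) and `header_row_count` (0 when absent, 2 or
#'   more for stacked header rows).
#' @export
detect_header <- function(region, sheet) {
  b <- region$bounds
  cols <- b$left:b$right
  row_info <- function(r) {
    kinds <- vapply(cols, function(cc) {
      cell <- get_cell(sheet, r, cc)
      if (is.null(cell)) "empty" else cell$kind
    }, character(1))
    values <- vapply(cols, function(cc) {
      cell <- get_cell(sheet, r, cc)
      if (is.null(cell) || cell$kind == "empty") NA_character_
      else as.character(cell$value)
    }, character(1))
    list(kinds = kinds, values = values)
  }
  qualifies <- function(info, need_unique) {
    all(info$kinds == "text") &&
      (!need_unique || !anyDuplicated(info$values))
  }
  first <- row_info(b$top)
  if (!qualifies(first, need_unique = TRUE)) {
    return(list(header_row = NA_integer_, header_row_count = 0L))
  }
  count <- 1L
  # non-text content per column strictly below the counted header rows
  non_text_below <- function(n_header) {
    vapply(cols, function(cc) {
      rows <- if (b$top + n_header > b$bottom) integer() else
        (b$top + n_header):b$bottom
      any(vapply(rows, function(r) {
        cell <- get_cell(sheet, r, cc)
        !is.null(cell) && !cell$kind %in% c("empty", "text")
      }, logical(1)))
    }, logical(1))
  }
  repeat {
    r <- b$top + count
    if (r > b$bottom) break
    if (sum(non_text_below(count)) < length(cols) / 2) break
    info <- row_info(r)
    if (!qualifies(info, need_unique = FALSE)) break
    count <- count + 1L
  }
  list(header_row = b$top, header_row_count = count)
}

#' @export
print.table_region <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("<region> %s!%s header_rows=%d\n", x$sheet_name,
              range_ref(b$top, b$left, b$bottom, b$right),
              x$header_row_count))
  invisible(x)
}

# all regions of a workbook, named by sheet
workbook_regions <- function(wb) {
  out <- lapply(wb$sheets, detect_regions)
  names(out) <- sheet_names(wb)
  out
}
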