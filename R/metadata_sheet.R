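#' Embed a metadata record as a spreadsheet tab
#'
#' Appends (or replaces) a sheet named `"Metadata"` holding the record as
#' element-name/value rows in schema order, followed by a table of
#' attribute-level metadata. The element display names are the stable keys:
#' [extract_metadata_sheet()] reconstructs an equal record from the sheet, so
#' metadata can travel inside the spreadsheet file itself and survive a
#' save/reopen cycle. Data sheets are untouched.
#'
#' @param wb a `wb_workbook`.
#' @param md a `metadata_record`.
#' @return `embed_metadata_sheet()` the workbook with the `"Metadata"` sheet;
#'   `extract_metadata_sheet()` the reconstructed `metadata_record`.
#' @export
embed_metadata_sheet <- function(wb, md) {
  s <- schema_elements()
  file_s <- s[s$group != "attribute", ]
  sh <- new_sheet("Metadata")
  for (i in seq_len(nrow(file_s))) {
    sh <- set_cell(sh, i, 1L, file_s$name[i], as_text = TRUE)
    v <- md$file_level[[file_s$id[i]]]
    if (!is.null(v)) {
      sh <- set_cell(sh, i, 2L, paste(v, collapse = "; "), as_text = TRUE)
    }
  }
  base <- nrow(file_s) + 2L
  attr_s <- s[s$group == "attribute", ]
  for (j in seq_len(nrow(attr_s))) {
    sh <- set_cell(sh, base, j, attr_s$name[j], as_text = TRUE)
  }
  sh <- set_cell(sh, base, nrow(attr_s) + 1L, "Column index", as_text = TRUE)
  if (nrow(md$attributes) > 0) {
    fields <- c("parameter_name", "description", "units",
                "measurement_type", "missing_value_code")
    for (i in seq_len(nrow(md$attributes))) {
      for (j in seq_along(fields)) {
        v <- md$attributes[[fields[j]]][i]
        if (nzchar(v)) sh <- set_cell(sh, base + i, j, v, as_text = TRUE)
      }
      sh <- set_cell(sh, base + i, length(fields) + 1L,
                     as.numeric(md$attributes$column_index[i]))
    }
  }
  add_sheet(wb, sh)
}

#' @rdname embed_metadata_sheet
#' @export
extract_metadata_sheet <- function(wb) {
  if (!"Metadata" %in% sheet_names(wb)) {
    stop("workbook has no 'Metadata' sheet", call. = FALSE)
  }
  sh <- sheet_by_name(wb, "Metadata")
  s <- schema_elements()
  file_s <- s[s$group != "attribute", ]
  fl <- list()
  for (i in seq_len(nrow(file_s))) {
    name_cell <- get_cell(sh, i, 1L)
    if (is.null(name_cell) ||
        !identical(as.character(name_cell$value), file_s$name[i])) {
      stop("'Metadata' sheet row ", i, " does not match the schema layout",
           call. = FALSE)
    }
    v <- get_cell(sh, i, 2L)
    if (!is.null(v) && v$kind != "empty") {
      value <- as.character(v$value)
      if (file_s$id[i] == "keywords") {
        value <- strsplit(value, "; ", fixed = TRUE)[[1]]
      }
      fl[[file_s$id[i]]] <- value
    }
  }
  base <- nrow(file_s) + 2L
  fields <- c("parameter_name", "description", "units",
              "measurement_type", "missing_value_code")
  attributes <- NULL
  i <- 1L
  repeat {
    idx_cell <- get_cell(sh, base + i, length(fields) + 1L)
    if (is.null(idx_cell) || idx_cell$kind == "empty") break
    row <- lapply(seq_along(fields), function(j) {
      v <- get_cell(sh, base + i, j)
      if (is.null(v) || v$kind == "empty") "" else as.character(v$value)
    })
    names(row) <- fields
    row$column_index <- as.integer(idx_cell$value)
    attributes <- rbind(attributes,
                        as.data.frame(row, stringsAsFactors = FALSE))
    i <- i + 1L
  }
  new_metadata(fl, attributes)
}
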