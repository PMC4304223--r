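#' Metadata records
#'
#' A metadata record pairs file-level descriptions (the non-attribute
#' elements of [schema_elements()], stored as a named list of character
#' values keyed by element id; `keywords` may hold several values) with
#' attribute-level descriptions of the data table's columns (one row per
#' column: `parameter_name`, `description`, `units`, `measurement_type`,
#' `missing_value_code`, `column_index`). Empty strings are normalized away,
#' so "present" and "non-empty" coincide.
#'
#' @param file_level named list of file-level element values.
#' @param attributes data.frame of attribute stubs (see
#'   [attributes_from_header()]); `NULL` for none.
#' @return a `metadata_record`.
#' @export
new_metadata <- function(file_level = list(), attributes = NULL) {
  unknown <- setdiff(names(file_level), file_level_ids())
  if (length(unknown) > 0) {
    stop("unknown metadata element id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  file_level <- Filter(function(v) length(v) > 0 && any(nzchar(v) & !is.na(v)),
                       lapply(file_level, as.character))
  # keep schema order
  file_level <- file_level[intersect(file_level_ids(), names(file_level))]
  if (is.null(attributes)) attributes <- empty_attributes()
  structure(list(file_level = file_level, attributes = attributes),
            class = "metadata_record")
}

empty_attributes <- function() {
  data.frame(parameter_name = character(), description = character(),
             units = character(), measurement_type = character(),
             missing_value_code = character(), column_index = integer(),
             stringsAsFactors = FALSE)
}

#' @rdname new_metadata
#' @param md a `metadata_record`.
#' @export
is_complete <- function(md) {
  all(required_ids() %in% names(md$file_level))
}

#' @rdname new_metadata
#' @param ... named element values to set (`NULL` to unset).
#' @export
set_elements <- function(md, ...) {
  updates <- list(...)
  fl <- md$file_level
  for (nm in names(updates)) fl[[nm]] <- updates[[nm]]
  new_metadata(fl, md$attributes)
}

#' @export
print.metadata_record <- function(x, ...) {
  cat("<metadata record>", length(x$file_level), "file-level element(s),",
      nrow(x$attributes), "attribute(s),",
      if (is_complete(x)) "complete" else "incomplete", "\n")
  invisible(x)
}

#' Pre-populate metadata from a workbook's document properties
#'
#' Spreadsheet files carry authorship information that can seed the metadata
#' form: today's date is filled in, the creator's first/last name are split
#' from the document author at the last whitespace, and the dataset title
#' falls back from the document title to the source file stem. Everything
#' else is left for the user.
#'
#' @param wb a `wb_workbook`.
#' @return a partial `metadata_record`.
#' @export
prepopulate <- function(wb) {
  fl <- list(today_date = format(Sys.Date(), "%Y-%m-%d"))
  author <- wb$doc_properties$author
  if (!is.null(author) && nzchar(trimws(author))) {
    author <- trimws(author)
    m <- regmatches(author, regexec("^(.*\\S)\\s+(\\S+)$", author))[[1]]
    if (length(m) == 3) {
      fl$creator_first_name <- m[2]
      fl$creator_last_name <- m[3]
    } else {
      fl$creator_last_name <- author
    }
  }
  title <- wb$doc_properties$title
  if (is.null(title) || !nzchar(trimws(title))) {
    title <- if (!is.na(wb$source_path)) {
      sub("\\.[^.]*$", "", basename(wb$source_path))
    } else NULL
  }
  if (!is.null(title)) fl$title <- title
  new_metadata(fl)
}

#' Attribute metadata stubs from a detected header row
#'
#' @param region a `table_region` with a detected header.
#' @param sheet the sheet the region lives on.
#' @return a data.frame of attribute stubs, one per column in column order,
#'   with `parameter_name` taken from the header cells and the descriptive
#'   fields left empty for the user.
#' @export
attributes_from_header <- function(region, sheet) {
  if (region$header_row_count < 1 || is.na(region$header_row)) {
    stop("no header row detected for this table; create a header row with ",
         "unique parameter names that describe the column's contents",
         call. = FALSE)
  }
  b <- region$bounds
  cols <- b$left:b$right
  names <- vapply(cols, function(cc) {
    cell <- get_cell(sheet, region$header_row, cc)
    as.character(cell$value)
  }, character(1))
  data.frame(parameter_name = names, description = "", units = "",
             measurement_type = "", missing_value_code = "",
             column_index = seq_along(cols), stringsAsFactors = FALSE)
}

#' Validate a metadata record
#'
#' Produces one finding per missing required element and one per invariant
#' violation: malformed dates (ISO 8601 expected), an email without `"@"`,
#' bounding coordinates out of range or with south above north / west and
#' east outside \[-180, 180\], and attribute stubs without a parameter name.
#' An empty result means the record is complete and valid.
#'
#' @param md a `metadata_record`.
#' @return a data.frame of findings (`element`, `problem`); zero rows when
#'   complete and valid.
#' @export
validate_metadata <- function(md) {
  findings <- list()
  add <- function(element, problem) {
    findings[[length(findings) + 1]] <<- data.frame(
      element = element, problem = problem, stringsAsFactors = FALSE)
  }
  s <- schema_elements()
  for (id in required_ids()) {
    if (!id %in% names(md$file_level)) {
      add(s$name[s$id == id], "required element is missing")
    }
  }
  for (id in c("today_date", "temporal_begin", "temporal_end")) {
    v <- md$file_level[[id]]
    if (!is.null(v) && !is_iso_date(v)) {
      add(s$name[s$id == id], paste0("not an ISO 8601 date: '", v, "'"))
    }
  }
  for (id in c("creator_email", "contact_email")) {
    v <- md$file_level[[id]]
    if (!is.null(v) && !grepl("@", v, fixed = TRUE)) {
      add(s$name[s$id == id], paste0("not an email address: '", v, "'"))
    }
  }
  coord <- function(id) {
    v <- md$file_level[[id]]
    if (is.null(v)) return(NA_real_)
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) add(s$name[s$id == id], paste0("not a number: '", v, "'"))
    num
  }
  w <- coord("west_bounding"); e <- coord("east_bounding")
  n <- coord("north_bounding"); so <- coord("south_bounding")
  for (v in list(c("west_bounding", w), c("east_bounding", e))) {
    num <- as.numeric(v[2])
    if (!is.na(num) && (num < -180 || num > 180)) {
      add(s$name[s$id == v[1]], "longitude outside [-180, 180]")
    }
  }
  for (v in list(c("north_bounding", n), c("south_bounding", so))) {
    num <- as.numeric(v[2])
    if (!is.na(num) && (num < -90 || num > 90)) {
      add(s$name[s$id == v[1]], "latitude outside [-90, 90]")
    }
  }
  if (!is.na(n) && !is.na(so) && so > n) {
    add("South bounding coordinate",
        "south bounding coordinate exceeds north bounding coordinate")
  }
  if (nrow(md$attributes) > 0) {
    noname <- which(!nzchar(md$attributes$parameter_name))
    for (i in noname) {
      add("Parameter name", paste0("attribute ", i, " has no parameter name"))
    }
  }
  if (length(findings) == 0) {
    data.frame(element = character(), problem = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
}
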