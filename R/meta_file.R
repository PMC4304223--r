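#' Plain-text metadata entry files
#'
#' The CLI exchanges metadata as a simple documented key-value text file:
#' one `element_id: value` line per file-level element (ids from
#' [schema_elements()]; keywords separated by `"; "`), and
#' `attribute.<i>.<field>: value` lines for column-level metadata (fields
#' `parameter_name`, `description`, `units`, `measurement_type`,
#' `missing_value_code`). Lines starting with `#` and blank lines are
#' ignored; empty values mean "not provided". [write_metadata_file()] emits
#' every element (empty ones included, grouped and commented) so the file
#' doubles as the fill-in template the `metadata init` command produces.
#'
#' @param md a `metadata_record`.
#' @param path file path.
#' @return `read_metadata_file()` a `metadata_record`;
#'   `write_metadata_file()` `path` invisibly.
#' @export
write_metadata_file <- function(md, path) {
  s <- schema_elements()
  lines <- c("# metadata entry file: fill in values after the colons.",
             "# required elements are marked with '# *'.")
  for (grp in c("basic", "personnel", "dataset")) {
    lines <- c(lines, "", paste0("# -- ", grp, " --"))
    for (i in which(s$group == grp)) {
      v <- md$file_level[[s$id[i]]]
      lines <- c(lines,
        paste0(if (s$required[i]) "# * " else "# ", s$name[i]),
        paste0(s$id[i], ": ",
               if (is.null(v)) "" else paste(v, collapse = "; ")))
    }
  }
  if (nrow(md$attributes) > 0) {
    lines <- c(lines, "", "# -- column attributes --")
    fields <- c("parameter_name", "description", "units",
                "measurement_type", "missing_value_code")
    for (i in seq_len(nrow(md$attributes))) {
      for (f in fields) {
        lines <- c(lines, sprintf("attribute.%d.%s: %s", i, f,
                                  md$attributes[[f]][i]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_metadata_file
#' @export
read_metadata_file <- function(path) {
  if (!file.exists(path)) {
    stop("metadata file not found: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.]+):\\s*(.*)$", lines))
  bad <- which(vapply(m, length, integer(1)) != 3)
  if (length(bad) > 0) {
    stop("cannot parse metadata file line: '", lines[bad[1]], "'",
         call. = FALSE)
  }
  keys <- vapply(m, `[`, character(1), 2)
  values <- trimws(vapply(m, `[`, character(1), 3))
  fl <- list()
  attr_rows <- list()
  for (i in seq_along(keys)) {
    if (!nzchar(values[i])) next
    am <- regmatches(keys[i], regexec("^attribute\\.([0-9]+)\\.([a-z_]+)$",
                                      keys[i]))[[1]]
    if (length(am) == 3) {
      idx <- am[2]
      row <- attr_rows[[idx]] %||% list()
      row[[am[3]]] <- values[i]
      attr_rows[[idx]] <- row
    } else if (keys[i] %in% file_level_ids()) {
      fl[[keys[i]]] <- if (keys[i] == "keywords") {
        strsplit(values[i], ";\\s*")[[1]]
      } else values[i]
    } else {
      stop("unknown metadata element id '", keys[i], "' in ", path,
           call. = FALSE)
    }
  }
  attributes <- NULL
  if (length(attr_rows) > 0) {
    idx <- sort(as.integer(names(attr_rows)))
    fields <- c("parameter_name", "description", "units",
                "measurement_type", "missing_value_code")
    attributes <- do.call(rbind, lapply(idx, function(i) {
      row <- attr_rows[[as.character(i)]]
      out <- lapply(fields, function(f) row[[f]] %||% "")
      names(out) <- fields
      out$column_index <- i
      as.data.frame(out, stringsAsFactors = FALSE)
    }))
  }
  new_metadata(fl, attributes)
}
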