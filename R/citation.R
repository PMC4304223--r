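#' Build a data citation from a metadata record
#'
#' The citation follows the DataCite citation style:
#' `Creator(s) (Year): Title. Publisher. Identifier.` with creators rendered
#' `"Last, First"` and joined by `"; "`. The publisher comes from the
#' record's data-publisher element, falling back to a default repository
#' name. The formatted string is also written back into the record's
#' formatted-citation element so the citation becomes part of the metadata.
#'
#' @param md a complete `metadata_record`.
#' @param year publication year.
#' @param identifier optional `ark_identifier` (see [mint_ark()]).
#' @param default_publisher repository name used when the record has none.
#' @param creators optional ordered list of `list(first, last)` overriding
#'   the creator derived from the record, for multi-creator datasets.
#' @return a `data_citation`: `creators`, `year`, `title`, `publisher`,
#'   `identifier`, `formatted`, and `metadata` (the updated record).
#' @export
build_citation <- function(md, year, identifier = NULL,
                           default_publisher = "Example Data Repository",
                           creators = NULL) {
  if (!is_complete(md)) {
    findings <- validate_metadata(md)
    stop("metadata record is incomplete:\n",
         paste0("  - ", findings$element, ": ", findings$problem,
                collapse = "\n"), call. = FALSE)
  }
  if (!is.null(identifier) && is.character(identifier)) {
    identifier <- validate_ark(identifier)$identifier
  }
  # only creator name fields cite; the data contact person is not a creator
  if (is.null(creators)) {
    creators <- list(list(first = md$file_level$creator_first_name,
                          last = md$file_level$creator_last_name))
  }
  publisher <- md$file_level$publisher %||% default_publisher
  joined <- paste(vapply(creators, function(p) {
    if (is.null(p$first)) p$last else paste0(p$last, ", ", p$first)
  }, character(1)), collapse = "; ")
  formatted <- sprintf("%s (%d): %s. %s.%s", joined, as.integer(year),
                       md$file_level$title, publisher,
                       if (is.null(identifier)) "" else
                         paste0(" ", identifier$full, "."))
  md <- set_elements(md, citation = formatted,
                     identifier = if (is.null(identifier)) NULL else
                       identifier$full)
  structure(
    list(creators = creators, year = as.integer(year),
         title = md$file_level$title, publisher = publisher,
         identifier = identifier, formatted = formatted, metadata = md),
    class = "data_citation")
}

#' @export
print.data_citation <- function(x, ...) {
  cat(x$formatted, "\n")
  invisible(x)
}

#' Export a citation in a standard bibliographic format
#'
#' Three formats are supported: RIS (`TY  - DATA` record with
#' `AU`/`PY`/`TI`/`PB`/`ID` tags and an `ER` terminator), BibTeX (a single
#' `@misc` entry with a stable `surname_year` key and the identifier in
#' `note`), and a DataCite-style XML `resource` with
#' `creators`/`titles`/`publisher`/`publicationYear`/`identifier`. All three
#' embed the same creator/title/year/identifier content.
#'
#' @param citation a `data_citation`.
#' @param format `"ris"`, `"bib"` or `"xml"`.
#' @param path optional output file.
#' @return the document as a single string (invisibly when `path` given).
#' @export
export_citation <- function(citation, format = c("ris", "bib", "xml"),
                            path = NULL) {
  if (!is.character(format) || !format[1] %in% c("ris", "bib", "xml")) {
    stop("unknown citation format '", format[1],
         "': expected \"ris\", \"bib\" or \"xml\"", call. = FALSE)
  }
  format <- format[1]
  id_str <- if (is.null(citation$identifier)) NULL else citation$identifier$full
  doc <- switch(format,
    ris = {
      au <- vapply(citation$creators, function(p) {
        paste0("AU  - ", if (is.null(p$first)) p$last else
               paste0(p$last, ", ", p$first))
      }, character(1))
      paste(c("TY  - DATA", au,
              paste0("PY  - ", citation$year),
              paste0("TI  - ", citation$title),
              paste0("PB  - ", citation$publisher),
              if (!is.null(id_str)) paste0("ID  - ", id_str),
              "ER  - ", ""), collapse = "\n")
    },
    bib = {
      key <- paste0(tolower(gsub("[^A-Za-z0-9]", "",
                                 citation$creators[[1]]$last)),
                    "_", citation$year)
      authors <- paste(vapply(citation$creators, function(p) {
        if (is.null(p$first)) p$last else paste0(p$last, ", ", p$first)
      }, character(1)), collapse = " and ")
      bb <- function(field, value) sprintf("  %s = {%s},", field, value)
      paste(c(paste0("@misc{", key, ","),
              bb("author", authors),
              bb("year", citation$year),
              bb("title", citation$title),
              bb("publisher", citation$publisher),
              if (!is.null(id_str)) bb("note", id_str),
              "}", ""), collapse = "\n")
    },
    xml = {
      creators <- paste0(vapply(citation$creators, function(p) {
        nm <- if (is.null(p$first)) p$last else paste0(p$last, ", ", p$first)
        paste0("<creator><creatorName>", xml_escape(nm),
               "</creatorName></creator>")
      }, character(1)), collapse = "")
      paste0(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
        "<resource>",
        if (!is.null(id_str)) paste0(
          "<identifier identifierType=\"ARK\">", xml_escape(id_str),
          "</identifier>") else "",
        "<creators>", creators, "</creators>",
        "<titles><title>", xml_escape(citation$title), "</title></titles>",
        "<publisher>", xml_escape(citation$publisher), "</publisher>",
        "<publicationYear>", citation$year, "</publicationYear>",
        "<resourceType resourceTypeGeneral=\"Dataset\">Dataset</resourceType>",
        "</resource>")
    })
  if (!is.null(path)) {
    writeLines(doc, path, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
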