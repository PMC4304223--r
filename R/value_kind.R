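#' Classify a raw cell value into a value kind
#'
#' Every cell value belongs to exactly one of six kinds: `empty`, `number`,
#' `text`, `date`, `boolean`, or `error`. Classification is total and
#' deterministic: the same input always yields the same kind. Native R types
#' map directly (`numeric` to `number`, `logical` to `boolean`, `Date` to
#' `date`). Character input -- the case that matters when sniffing CSV cells,
#' where everything arrives as text -- is classified `number` if and only if
#' it parses as a plain decimal or scientific-notation literal, `date` if it
#' is a valid ISO 8601 calendar date (`YYYY-MM-DD`), and `text` otherwise.
#' `NA`, `NULL` and the empty string are `empty`.
#'
#' @param raw a scalar value (or `NULL`).
#' @return one of `"empty"`, `"number"`, `"text"`, `"date"`, `"boolean"`,
#'   `"error"`.
#' @examples
#' value_kind_of("3.14")        # "number"
#' value_kind_of("2011-08-01")  # "date"
#' value_kind_of("n/a")         # "text"
#' @export
value_kind_of <- function(raw) {
  if (is.null(raw) || length(raw) == 0) return("empty")
  if (length(raw) != 1) stop("value_kind_of() expects a scalar", call. = FALSE)
  if (inherits(raw, "Date")) {
    return(if (is.na(raw)) "empty" else "date")
  }
  if (is.logical(raw)) return(if (is.na(raw)) "empty" else "boolean")
  if (is.numeric(raw)) return(if (is.na(raw)) "empty" else "number")
  if (is.character(raw)) {
    if (is.na(raw) || !nzchar(raw)) return("empty")
    if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", raw)) {
      return("number")
    }
    if (is_iso_date(raw)) return("date")
    return("text")
  }
  "error"
}

is_iso_date <- function(s) {
  grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", s) &&
    !is.na(suppressWarnings(as.Date(s, format = "%Y-%m-%d")))
}

# coerce a sniffed CSV string to its native value per its kind
sniff_value <- function(s) {
  kind <- value_kind_of(s)
  value <- switch(kind,
    empty = NA,
    number = as.numeric(s),
    date = as.Date(s),
    s
  )
  list(value = value, kind = kind)
}
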