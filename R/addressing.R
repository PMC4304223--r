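#' A1-style cell addressing
#'
#' Spreadsheet cells are addressed 1-based by `(row, column)` internally and
#' rendered in the familiar A1 notation (column letters, then row number) for
#' display, e.g. `B3` is row 3, column 2. The two renderings are bijective.
#'
#' @param col,row positive integer scalars or vectors.
#' @param a1 character vector of A1 references such as `"B3"`.
#' @return `col_letter()` returns column letters; `a1()` returns A1 strings;
#'   `parse_a1()` returns a list with integer vectors `row` and `col`.
#' @examples
#' a1(3, 2)          # "B3"
#' parse_a1("AA10")  # row 10, col 27
#' @name addressing
NULL

#' @rdname addressing
#' @export
col_letter <- function(col) {
  stopifnot(all(col >= 1))
  vapply(as.integer(col), function(n) {
    s <- ""
    while (n > 0) {
      r <- (n - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    s
  }, character(1))
}

#' @rdname addressing
#' @export
col_number <- function(letters) {
  vapply(toupper(letters), function(s) {
    chars <- strsplit(s, "")[[1]]
    sum((match(chars, LETTERS)) * 26^(rev(seq_along(chars)) - 1))
  }, numeric(1), USE.NAMES = FALSE) |> as.integer()
}

#' @rdname addressing
#' @export
a1 <- function(row, col) paste0(col_letter(col), row)

#' @rdname addressing
#' @export
parse_a1 <- function(a1) {
  m <- regmatches(a1, regexec("^\\$?([A-Za-z]+)\\$?([0-9]+)$", a1))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("not an A1 cell reference: ", a1[bad][1], call. = FALSE)
  list(
    row = as.integer(vapply(m, `[`, character(1), 3)),
    col = col_number(vapply(m, `[`, character(1), 2))
  )
}

# "B2:C3" -> list(top, left, bottom, right); a single cell ref is a 1x1 range
parse_range <- function(ref) {
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1) parts <- c(parts, parts)
  p1 <- parse_a1(parts[1]); p2 <- parse_a1(parts[2])
  list(
    top = min(p1$row, p2$row), left = min(p1$col, p2$col),
    bottom = max(p1$row, p2$row), right = max(p1$col, p2$col)
  )
}

range_ref <- function(top, left, bottom, right) {
  if (top == bottom && left == right) a1(top, left)
  else paste0(a1(top, left), ":", a1(bottom, right))
}
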