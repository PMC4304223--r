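#' The best-practices rule catalogue
#'
#' Eleven closed rules describe spreadsheet features that break CSV export or
#' machine readability, each with a "why it is a problem" paragraph and a
#' suggested remedy shown to the user verbatim in reports. The catalogue
#' order is fixed and rule identifiers form a closed set -- checkers, report
#' rendering and the fixture generator all key on these ids.
#'
#' Two choices the catalogue documents explicitly because the source
#' best-practice texts leave them open: the allowed character set for the
#' special-characters rule is ASCII letters, digits, space and `. _ - ( ) /`
#' (parentheses, slash, period, underscore and hyphen are admitted as
#' archival-safe), with the comma excluded here because it is owned by the
#' commas rule; and the duplicate-header-label finding is folded under
#' `header_problem` rather than becoming a twelfth rule.
#'
#' @return a data.frame with one row per rule: `rule_id`, `title`, `why`,
#'   `remedy`, `auto_fixable`, `severity` (all rules `"warning"` except
#'   `multiple_sheets`, which is `"info"` because export handles it
#'   automatically).
#' @examples
#' rule_catalogue()$rule_id
#' @export
rule_catalogue <- function() {
  data.frame(
    rule_id = c("embedded_objects", "embedded_comments", "commas",
                "special_characters", "color_coding", "mixed_types",
                "non_contiguous", "merged_cells", "blank_cells",
                "header_problem", "multiple_sheets"),
    title = c(
      "Embedded charts, tables, pictures.",
      "Embedded comments.",
      "Commas.",
      "Special characters.",
      "Color coded text or cell shading.",
      "Columns have mixed data types.",
      "Non-contiguous data.",
      "Merged cells.",
      "Blank cells.",
      "Header row absent or more than one header row.",
      "Multiple sheets (tabs)."),
    why = c(
      "These embedded items will not be visible when data are exported as a .csv file. Also, these elements are visible only if the file is opened with Microsoft Excel.",
      "Comments will not be visible when data are exported as a .csv file. Also, these elements are visible only if the file is opened with Microsoft Excel.",
      "Commas are often used to separate multiple piece of information/data (e.g. City, State). Cells only contain one piece of information.",
      "Special characters may cause problems for other programs or may be modified upon export.",
      "Formatting will not be visible when data are exported as a .csv file. If formatting is used as a coding scheme, all codes will be lost upon export.",
      "Some programs cannot handle mixed data types (e.g. numbers and text in the same column).",
      "Empty columns or rows tend to be used to separate multiple data tables on the same tab.",
      "Merged cells will not be maintained when data are exported as a .csv file. Information may be lost when cells are un-merged upon export.",
      "Blank cells within a contiguous data table are potentially problematic for reading files in other programs.",
      "Ideally the first row of a data table contains parameter names for the columns. If there is no header row, your data table may be difficult to use and document. If there are multiple header rows, some software programs may have problems.",
      "Multiple sheets will not be maintained as a single document if the file is converted to .csv."),
    remedy = c(
      "Move embedded charts, tables, or pictures to other tabs in your file or to a completely separate file.",
      "Create a new column titled “Comments” and add your text there.",
      "Split pieces of information into multiple columns (e.g. City column and State column).",
      "Use alpha-numeric characters only. If needed, describe the symbol in a new column.",
      "Use descriptions or alphanumeric coding schemes in a new column.",
      "Ensure you are using only numbers or only text in a column; split data into multiple columns if necessary.",
      "Move multiple tables onto separate tabs.",
      "Un-merge cells and annotate appropriately so information is not lost.",
      "Designate a coding scheme for missing data or other explanations for blank cells.",
      "Create a header row with unique parameter names that describe the column’s contents.",
      "The user can move each tab into a separate .csv file. If left as multiple sheets, the tool will automatically export the data as separate .csv files."),
    auto_fixable = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                     FALSE, TRUE, FALSE, FALSE, TRUE),
    severity = c(rep("warning", 10), "info"),
    stringsAsFactors = FALSE
  )
}

#' @rdname rule_catalogue
#' @export
rule_ids <- function() rule_catalogue()$rule_id

# characters admitted by the special-characters rule (comma handled by the
# commas rule; quote/apostrophe NOT admitted)
SPECIAL_ALLOWED_PATTERN <- "^[A-Za-z0-9 ._()/-]*$"

new_issue <- function(rule_id, sheet, locations, detail = NA_character_) {
  cat_row <- rule_catalogue()[rule_catalogue()$rule_id == rule_id, ]
  if (nrow(cat_row) != 1) stop("unknown rule id: ", rule_id, call. = FALSE)
  structure(
    list(rule_id = rule_id, sheet = sheet,
         locations = as.character(locations),
         why = cat_row$why, remedy = cat_row$remedy,
         auto_fixable = cat_row$auto_fixable, severity = cat_row$severity,
         detail = detail),
    class = "bp_issue")
}
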