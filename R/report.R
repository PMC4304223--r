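#' Render a check report as text or JSON
#'
#' The text form is the human-readable report a user downloads: a summary
#' line, then each issue with its sheet, locations, the catalogue's "Why"
#' paragraph and the suggested remedy. The JSON form is schema-stable
#' (`source`, `checked_at`, `issues[]`, `per_rule_counts`, `passed`) and
#' round-trips through [parse_report()].
#'
#' @param report a `check_report` from [run_all_checks()].
#' @param format `"text"` or `"json"`.
#' @return a single string.
#' @export
render_report <- function(report, format = c("text", "json")) {
  if (!is.character(format) || !format[1] %in% c("text", "json")) {
    stop("unknown report format '", format[1],
         "': expected \"text\" or \"json\"", call. = FALSE)
  }
  format <- format[1]
  if (format == "json") {
    issues <- lapply(report$issues, function(is) {
      list(rule_id = is$rule_id, sheet = is$sheet,
           locations = as.list(is$locations), why = is$why,
           remedy = is$remedy, auto_fixable = is$auto_fixable,
           severity = is$severity,
           detail = if (is.na(is$detail)) NULL else is$detail)
    })
    return(jsonlite::toJSON(list(
      source = report$source, checked_at = report$checked_at,
      issues = issues,
      per_rule_counts = as.list(report$per_rule_counts),
      passed = report$passed), auto_unbox = TRUE, pretty = TRUE))
  }
  lines <- c(
    "Best practices check report",
    paste0("Source: ", report$source),
    paste0("Checked at: ", report$checked_at),
    sprintf("Result: %s (%d issue%s)",
            if (report$passed) "PASSED" else "issues found",
            length(report$issues),
            if (length(report$issues) == 1) "" else "s"),
    "")
  cat_df <- rule_catalogue()
  for (is in report$issues) {
    title <- cat_df$title[cat_df$rule_id == is$rule_id]
    lines <- c(lines,
      sprintf("[%s] %s (sheet: %s)", is$severity, title, is$sheet),
      paste0("  Locations: ", paste(is$locations, collapse = ", ")),
      paste0("  Why: ", is$why),
      paste0("  Suggested remedy: ", is$remedy),
      if (!is.na(is$detail)) paste0("  Detail: ", is$detail),
      "")
  }
  paste(lines, collapse = "\n")
}

#' @rdname render_report
#' @param json a JSON string produced by `render_report(report, "json")`.
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  issues <- lapply(x$issues, function(is) {
    structure(
      list(rule_id = is$rule_id, sheet = is$sheet,
           locations = unlist(is$locations) %||% character(),
           why = is$why, remedy = is$remedy,
           auto_fixable = is$auto_fixable, severity = is$severity,
           detail = is$detail %||% NA_character_),
      class = "bp_issue")
  })
  structure(
    list(source = x$source, checked_at = x$checked_at, issues = issues,
         per_rule_counts = stats::setNames(
           as.integer(unlist(x$per_rule_counts)), names(x$per_rule_counts)),
         passed = x$passed),
    class = "check_report")
}
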