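# SpreadsheetML (.xlsx) reader built on unzip + xml2.
#
# Namespace handling uses local-name() XPath throughout so files written by
# this package, openpyxl or Excel parse alike. Shared strings, inline strings
# and cached formula strings are all supported; explicit t="d" ISO dates are
# read as dates (date-as-serial-number cells, which require number-format
# interpretation, are read as numbers and noted as a limitation).

xp <- function(node, path) xml2::xml_find_all(node, path)
xp1 <- function(node, path) xml2::xml_find_first(node, path)
lname <- function(tag) sprintf("*[local-name()='%s']", tag)

read_rels <- function(dir, part) {
  rels_path <- file.path(dir, dirname(part), "_rels", paste0(basename(part), ".rels"))
  if (!file.exists(rels_path)) {
    return(data.frame(id = character(), type = character(),
                      target = character(), stringsAsFactors = FALSE))
  }
  doc <- xml2::read_xml(rels_path)
  rels <- xp(doc, paste0("//", lname("Relationship")))
  data.frame(
    id = xml2::xml_attr(rels, "Id"),
    type = xml2::xml_attr(rels, "Type"),
    target = xml2::xml_attr(rels, "Target"),
    stringsAsFactors = FALSE
  )
}

# resolve a relationship target relative to the part that declared it
resolve_target <- function(part, target) {
  if (startsWith(target, "/")) return(sub("^/", "", target))
  base <- dirname(part)
  pieces <- c(if (base != ".") strsplit(base, "/")[[1]],
              strsplit(target, "/")[[1]])
  out <- character()
  for (p in pieces) {
    if (p == "..") out <- out[-length(out)]
    else if (p != ".") out <- c(out, p)
  }
  paste(out, collapse = "/")
}

# legacy indexed palette (subset: the colors Excel assigns by default)
INDEXED_COLORS <- c(
  "000000", "FFFFFF", "FF0000", "00FF00", "0000FF", "FFFF00", "FF00FF",
  "00FFFF", "000000", "FFFFFF", "FF0000", "00FF00", "0000FF", "FFFF00",
  "FF00FF", "00FFFF", "800000", "008000", "000080", "808000", "800080",
  "008080", "C0C0C0", "808080", "9999FF", "993366", "FFFFCC", "CCFFFF",
  "660066", "FF8080", "0066CC", "CCCCFF", "000080", "FF00FF", "FFFF00",
  "00FFFF", "800080", "800000", "008080", "0000FF", "00CCFF", "CCFFFF",
  "CCFFCC", "FFFF99", "99CCFF", "FF99CC", "CC99FF", "FFCC99", "3366FF",
  "33CCCC", "99CC00", "FFCC00", "FF9900", "FF6600", "666699", "969696",
  "003366", "339966", "003300", "333300", "993300", "993366", "333399",
  "333333")

color_of <- function(node) {
  if (length(node) == 0 || is.na(node) ||
      inherits(node, "xml_missing")) return(NA_character_)
  rgb <- xml2::xml_attr(node, "rgb")
  if (!is.na(rgb)) return(norm_color(rgb))
  idx <- xml2::xml_attr(node, "indexed")
  if (!is.na(idx)) {
    i <- as.integer(idx) + 1L
    if (i >= 1 && i <= length(INDEXED_COLORS)) return(INDEXED_COLORS[i])
  }
  NA_character_  # theme colors unresolved -> treated as default
}

read_styles <- function(dir) {
  path <- file.path(dir, "xl", "styles.xml")
  if (!file.exists(path)) return(list())
  doc <- xml2::read_xml(path)
  fonts <- lapply(xp(doc, paste0("/*/", lname("fonts"), "/", lname("font"))),
                  function(f) color_of(xp1(f, lname("color"))))
  fills <- lapply(xp(doc, paste0("/*/", lname("fills"), "/", lname("fill"))),
                  function(f) {
    pf <- xp1(f, lname("patternFill"))
    if (inherits(pf, "xml_missing")) return(NA_character_)
    if (identical(xml2::xml_attr(pf, "patternType"), "none")) return(NA_character_)
    color_of(xp1(pf, lname("fgColor")))
  })
  xfs <- xp(doc, paste0("/*/", lname("cellXfs"), "/", lname("xf")))
  lapply(xfs, function(x) {
    font_i <- as.integer(xml2::xml_attr(x, "fontId"))
    fill_i <- as.integer(xml2::xml_attr(x, "fillId"))
    list(
      font = if (!is.na(font_i) && font_i + 1L <= length(fonts)) fonts[[font_i + 1L]] else NA_character_,
      fill = if (!is.na(fill_i) && fill_i + 1L <= length(fills)) fills[[fill_i + 1L]] else NA_character_
    )
  })
}

read_shared_strings <- function(dir) {
  path <- file.path(dir, "xl", "sharedStrings.xml")
  if (!file.exists(path)) return(character())
  doc <- xml2::read_xml(path)
  vapply(xp(doc, paste0("/*/", lname("si"))), function(si) {
    paste(xml2::xml_text(xp(si, paste0(".//", lname("t")))), collapse = "")
  }, character(1))
}

read_sheet_part <- function(dir, part, name, styles, shared) {
  doc <- xml2::read_xml(file.path(dir, part))
  sh <- new_sheet(name)
  for (c_node in xp(doc, paste0("//", lname("sheetData"), "/", lname("row"),
                                "/", lname("c")))) {
    ref <- xml2::xml_attr(c_node, "r")
    if (is.na(ref)) next
    pos <- parse_a1(ref)
    t_attr <- xml2::xml_attr(c_node, "t")
    v_node <- xp1(c_node, lname("v"))
    f_node <- xp1(c_node, lname("f"))
    is_node <- xp1(c_node, lname("is"))
    v_text <- if (!inherits(v_node, "xml_missing")) xml2::xml_text(v_node) else NA_character_
    value <- NULL
    if (!inherits(is_node, "xml_missing")) {
      value <- paste(xml2::xml_text(xp(is_node, paste0(".//", lname("t")))),
                     collapse = "")
    } else if (!is.na(v_text)) {
      value <- switch(ifelse(is.na(t_attr), "n", t_attr),
        s = shared[as.integer(v_text) + 1L],
        str = v_text,
        b = v_text %in% c("1", "true", "TRUE"),
        d = as.Date(substr(v_text, 1, 10)),
        e = v_text,
        as.numeric(v_text))
    }
    s_attr <- xml2::xml_attr(c_node, "s")
    style <- if (!is.na(s_attr) && as.integer(s_attr) + 1L <= length(styles)) {
      styles[[as.integer(s_attr) + 1L]]
    } else list(fill = NA_character_, font = NA_character_)
    has_style <- !is.na(style$fill) || !is.na(style$font)
    has_formula <- !inherits(f_node, "xml_missing")
    if (is.null(value) && !has_style && !has_formula) next
    sh <- set_cell(sh, pos$row, pos$col,
      value = value,
      formula = if (has_formula) xml2::xml_text(f_node) else NULL,
      fill = if (!is.na(style$fill)) style$fill else NULL,
      font_color = if (!is.na(style$font)) style$font else NULL,
      as_text = is.character(value) &&
        (identical(t_attr, "s") || identical(t_attr, "inlineStr") ||
         identical(t_attr, "str")))
    if (identical(t_attr, "e")) {
      i <- which(sh$cells$row == pos$row & sh$cells$col == pos$col)
      sh$cells$kind[i] <- "error"
    }
  }
  for (m in xp(doc, paste0("//", lname("mergeCell")))) {
    sh <- merge_cells(sh, xml2::xml_attr(m, "ref"))
  }
  # comments / drawings / pivot tables via the sheet's relationships
  rels <- read_rels(dir, part)
  for (i in seq_len(nrow(rels))) {
    target <- resolve_target(part, rels$target[i])
    if (grepl("/comments$", rels$type[i])) {
      cdoc <- xml2::read_xml(file.path(dir, target))
      for (cm in xp(cdoc, paste0("//", lname("comment")))) {
        pos <- parse_a1(xml2::xml_attr(cm, "ref"))
        txt <- paste(xml2::xml_text(xp(cm, paste0(".//", lname("t")))),
                     collapse = "")
        sh <- set_cell(sh, pos$row, pos$col, comment = txt)
      }
    } else if (grepl("/drawing$", rels$type[i])) {
      sh <- read_drawing(dir, target, sh)
    } else if (grepl("/pivotTable$", rels$type[i])) {
      pdoc <- xml2::read_xml(file.path(dir, target))
      loc <- xp1(pdoc, paste0("//", lname("location")))
      if (!inherits(loc, "xml_missing")) {
        pos <- parse_range(xml2::xml_attr(loc, "ref"))
        sh <- add_object(sh, "pivot_table", pos$top, pos$left)
      }
    }
  }
  sh
}

read_drawing <- function(dir, part, sh) {
  ddoc <- xml2::read_xml(file.path(dir, part))
  for (anchor in xp(ddoc, paste0(
      "//", lname("oneCellAnchor"), "|//", lname("twoCellAnchor"),
      "|//", lname("absoluteAnchor")))) {
    from <- xp1(anchor, lname("from"))
    if (inherits(from, "xml_missing")) next
    arow <- as.integer(xml2::xml_text(xp1(from, lname("row")))) + 1L
    acol <- as.integer(xml2::xml_text(xp1(from, lname("col")))) + 1L
    if (!inherits(xp1(anchor, paste0(".//", lname("graphicFrame"))), "xml_missing")) {
      sh <- add_object(sh, "chart", arow, acol)
    } else if (!inherits(xp1(anchor, paste0(".//", lname("pic"))), "xml_missing")) {
      sh <- add_object(sh, "picture", arow, acol)
    }
  }
  sh
}

read_doc_properties <- function(dir) {
  path <- file.path(dir, "docProps", "core.xml")
  if (!file.exists(path)) return(list())
  doc <- xml2::read_xml(path)
  grab <- function(tag) {
    n <- xp1(doc, paste0("//", lname(tag)))
    if (inherits(n, "xml_missing")) return(NULL)
    txt <- xml2::xml_text(n)
    if (nzchar(txt)) txt else NULL
  }
  props <- list(author = grab("creator"), title = grab("title"),
                created = grab("created"))
  props[!vapply(props, is.null, logical(1))]
}

read_xlsx_workbook <- function(path) {
  dir <- tempfile("xlsxr")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ok <- tryCatch({
    utils::unzip(path, exdir = dir)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !file.exists(file.path(dir, "xl", "workbook.xml"))) {
    stop("'", path, "' is not a readable .xlsx workbook", call. = FALSE)
  }
  wdoc <- xml2::read_xml(file.path(dir, "xl", "workbook.xml"))
  wrels <- read_rels(dir, "xl/workbook.xml")
  styles <- read_styles(dir)
  shared <- read_shared_strings(dir)
  sheets <- list()
  for (s_node in xp(wdoc, paste0("//", lname("sheet")))) {
    name <- xml2::xml_attr(s_node, "name")
    rid <- xml2::xml_attr(s_node, "id")  # r:id resolves by local name
    target <- wrels$target[wrels$id == rid]
    if (length(target) != 1) {
      stop("workbook part missing for sheet '", name, "'", call. = FALSE)
    }
    part <- resolve_target("xl/workbook.xml", target)
    sheets <- c(sheets, list(read_sheet_part(dir, part, name, styles, shared)))
  }
  new_workbook(sheets, doc_properties = read_doc_properties(dir),
               source_path = path, source_format = "xlsx")
}

read_csv_workbook <- function(path) {
  tbl <- tryCatch(
    suppressWarnings(readr::read_csv(
      path, col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
      na = character(), progress = FALSE, locale = readr::locale(encoding = "UTF-8"))),
    error = function(e) stop("cannot parse CSV file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  stem <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  sh <- new_sheet(stem)
  for (j in seq_len(ncol(tbl))) {
    column <- tbl[[j]]
    for (i in seq_along(column)) {
      raw <- column[i]
      if (is.na(raw) || !nzchar(raw)) next
      sv <- sniff_value(raw)
      sh <- set_cell(sh, i, j, value = sv$value,
                     as_text = sv$kind == "text")
    }
  }
  new_workbook(list(sh), source_path = path, source_format = "csv")
}

#' Read a workbook from disk
#'
#' Accepts `.xlsx` (Office Open XML) or `.csv` (RFC 4180; UTF-8 with BOM
#' tolerance). A CSV yields a one-sheet workbook named after the file stem,
#' with each cell's kind sniffed by [value_kind_of()] -- numeric-looking text
#' becomes a number, ISO-8601 dates become dates, everything else stays text.
#'
#' @param path path to an `.xlsx` or `.csv` file.
#' @return a `wb_workbook`.
#' @export
read_workbook <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    xlsx = read_xlsx_workbook(path),
    csv = read_csv_workbook(path),
    stop("unsupported file extension '.", ext,
         "': expected .xlsx or .csv", call. = FALSE))
}
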