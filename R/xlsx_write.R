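# Minimal SpreadsheetML (.xlsx) writer.
#
# Scope is exactly what the workbook model carries: cell values (numbers,
# inline-string text, ISO-8601 typed dates, booleans), cached formula values,
# comments, solid fills and font colors, merged ranges, document properties,
# and presence-plus-anchor stubs for charts, pictures and pivot tables.
# Embedded-object parts are minimal valid OOXML: enough for this package's
# reader (and for structural inspection), not guaranteed to render in Excel.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# shortest decimal rendering that survives a parse round-trip
num_to_str <- function(x) {
  if (is.na(x)) return("")
  if (is.finite(x) && x == floor(x) && abs(x) < 1e15) {
    return(sprintf("%.0f", x))
  }
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (suppressWarnings(as.numeric(s)) == x) return(s)
  }
  formatC(x, digits = 17, format = "g", width = -1)
}

XMLDECL <- "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>\n"
NS_MAIN <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
NS_REL <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"
NS_PKGREL <- "http://schemas.openxmlformats.org/package/2006/relationships"
REL_T <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"

# 1x1 transparent PNG used as the payload of picture stubs
png_stub <- function() {
  jsonlite::base64_dec(paste0(
    "iVBORw0KGgoAAAANSUhEUgAAAAEAAAABCAYAAAAfFcSJAAAADUlEQVR42mNkYPhf",
    "DwAChwGA60e6kgAAAABJRU5ErkJggg=="))
}

# collect unique (fill, font_color) pairs -> styles.xml + lookup keyed
# "fill|font" -> cellXfs index (0 = default)
build_styles <- function(wb) {
  pairs <- unique(do.call(rbind, c(list(data.frame(
    fill = character(), font = character(), stringsAsFactors = FALSE)),
    lapply(wb$sheets, function(sh) {
      cells <- sh$cells
      keep <- !is.na(cells$fill) | !is.na(cells$font_color)
      data.frame(fill = cells$fill[keep], font = cells$font_color[keep],
                 stringsAsFactors = FALSE)
    }))))
  fonts <- c(NA, unique(pairs$font[!is.na(pairs$font)]))
  fills <- c(NA, NA, unique(pairs$fill[!is.na(pairs$fill)]))  # 0 none, 1 gray125
  font_xml <- vapply(fonts, function(col) {
    if (is.na(col)) "<font><sz val=\"11\"/><name val=\"Calibri\"/></font>"
    else sprintf("<font><sz val=\"11\"/><color rgb=\"FF%s\"/><name val=\"Calibri\"/></font>", col)
  }, character(1))
  fill_xml <- c(
    "<fill><patternFill patternType=\"none\"/></fill>",
    "<fill><patternFill patternType=\"gray125\"/></fill>",
    vapply(fills[-(1:2)], function(col) sprintf(
      "<fill><patternFill patternType=\"solid\"><fgColor rgb=\"FF%s\"/><bgColor indexed=\"64\"/></patternFill></fill>",
      col), character(1)))
  xfs <- "<xf numFmtId=\"0\" fontId=\"0\" fillId=\"0\" borderId=\"0\"/>"
  lookup <- list()
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      font_id <- if (is.na(pairs$font[i])) 0L else match(pairs$font[i], fonts) - 1L
      fill_id <- if (is.na(pairs$fill[i])) 0L else match(pairs$fill[i], fills) - 1L
      xfs <- c(xfs, sprintf(
        "<xf numFmtId=\"0\" fontId=\"%d\" fillId=\"%d\" borderId=\"0\"%s%s/>",
        font_id, fill_id,
        if (fill_id > 0) " applyFill=\"1\"" else "",
        if (font_id > 0) " applyFont=\"1\"" else ""))
      lookup[[paste(pairs$fill[i], pairs$font[i], sep = "|")]] <- i
    }
  }
  xml <- paste0(
    XMLDECL, "<styleSheet xmlns=\"", NS_MAIN, "\">",
    "<fonts count=\"", length(font_xml), "\">", paste(font_xml, collapse = ""), "</fonts>",
    "<fills count=\"", length(fill_xml), "\">", paste(fill_xml, collapse = ""), "</fills>",
    "<borders count=\"1\"><border><left/><right/><top/><bottom/><diagonal/></border></borders>",
    "<cellStyleXfs count=\"1\"><xf numFmtId=\"0\" fontId=\"0\" fillId=\"0\" borderId=\"0\"/></cellStyleXfs>",
    "<cellXfs count=\"", length(xfs), "\">", paste(xfs, collapse = ""), "</cellXfs>",
    "</styleSheet>")
  list(xml = xml, lookup = lookup)
}

cell_xml <- function(row, col, value, kind, formula, s_idx) {
  ref <- a1(row, col)
  s_attr <- if (is.null(s_idx)) "" else sprintf(" s=\"%d\"", s_idx)
  f_part <- if (!is.na(formula)) paste0("<f>", xml_escape(formula), "</f>") else ""
  if (kind == "empty" && !nzchar(f_part)) {
    return(sprintf("<c r=\"%s\"%s/>", ref, s_attr))
  }
  body <- switch(kind,
    number = paste0(f_part, "<v>", num_to_str(value), "</v>"),
    text = if (nzchar(f_part)) {
      paste0(f_part, "<v>", xml_escape(value), "</v>")
    } else {
      paste0("<is><t xml:space=\"preserve\">", xml_escape(value), "</t></is>")
    },
    date = paste0(f_part, "<v>", format(value, "%Y-%m-%d"), "</v>"),
    boolean = paste0(f_part, "<v>", if (isTRUE(value)) "1" else "0", "</v>"),
    error = paste0(f_part, "<v>", xml_escape(as.character(value)), "</v>"),
    paste0(f_part, "<v></v>"))
  t_attr <- switch(kind,
    text = if (nzchar(f_part)) " t=\"str\"" else " t=\"inlineStr\"",
    date = " t=\"d\"", boolean = " t=\"b\"", error = " t=\"e\"", "")
  sprintf("<c r=\"%s\"%s%s>%s</c>", ref, s_attr, t_attr, body)
}

sheet_xml <- function(sh, style_lookup, has_drawing, drawing_rid) {
  cells <- sh$cells
  rows_xml <- character()
  if (nrow(cells) > 0) {
    for (r in sort(unique(cells$row))) {
      in_row <- cells[cells$row == r, , drop = FALSE]
      cs <- vapply(seq_len(nrow(in_row)), function(i) {
        key <- paste(in_row$fill[i], in_row$font_color[i], sep = "|")
        s_idx <- if (key == "NA|NA") NULL else style_lookup[[key]]
        cell_xml(in_row$row[i], in_row$col[i], in_row$value[[i]],
                 in_row$kind[i], in_row$formula[i], s_idx)
      }, character(1))
      rows_xml <- c(rows_xml, sprintf("<row r=\"%d\">%s</row>", r,
                                      paste(cs, collapse = "")))
    }
  }
  merge_part <- if (length(sh$merged) > 0) {
    paste0("<mergeCells count=\"", length(sh$merged), "\">",
           paste0("<mergeCell ref=\"", sh$merged, "\"/>", collapse = ""),
           "</mergeCells>")
  } else ""
  drawing_part <- if (has_drawing) {
    sprintf("<drawing r:id=\"%s\"/>", drawing_rid)
  } else ""
  paste0(
    XMLDECL, "<worksheet xmlns=\"", NS_MAIN, "\" xmlns:r=\"", NS_REL, "\">",
    "<sheetData>", paste(rows_xml, collapse = ""), "</sheetData>",
    merge_part, drawing_part, "</worksheet>")
}

comments_xml <- function(cells) {
  with_comment <- cells[!is.na(cells$comment), , drop = FALSE]
  items <- vapply(seq_len(nrow(with_comment)), function(i) sprintf(
    "<comment ref=\"%s\" authorId=\"0\"><text><t xml:space=\"preserve\">%s</t></text></comment>",
    a1(with_comment$row[i], with_comment$col[i]),
    xml_escape(with_comment$comment[i])), character(1))
  paste0(XMLDECL, "<comments xmlns=\"", NS_MAIN, "\">",
         "<authors><author/></authors>",
         "<commentList>", paste(items, collapse = ""), "</commentList>",
         "</comments>")
}

drawing_xml <- function(objects, rids) {
  anchors <- vapply(seq_len(nrow(objects)), function(i) {
    from <- sprintf(
      "<xdr:from><xdr:col>%d</xdr:col><xdr:colOff>0</xdr:colOff><xdr:row>%d</xdr:row><xdr:rowOff>0</xdr:rowOff></xdr:from>",
      objects$col[i] - 1L, objects$row[i] - 1L)
    body <- if (objects$kind[i] == "chart") sprintf(paste0(
      "<xdr:graphicFrame macro=\"\"><xdr:nvGraphicFramePr>",
      "<xdr:cNvPr id=\"%d\" name=\"Chart %d\"/><xdr:cNvGraphicFramePr/>",
      "</xdr:nvGraphicFramePr>",
      "<xdr:xfrm><a:off x=\"0\" y=\"0\"/><a:ext cx=\"0\" cy=\"0\"/></xdr:xfrm>",
      "<a:graphic><a:graphicData uri=\"http://schemas.openxmlformats.org/drawingml/2006/chart\">",
      "<c:chart xmlns:c=\"http://schemas.openxmlformats.org/drawingml/2006/chart\" r:id=\"%s\"/>",
      "</a:graphicData></a:graphic></xdr:graphicFrame>"),
      i, i, rids[i])
    else sprintf(paste0(
      "<xdr:pic><xdr:nvPicPr><xdr:cNvPr id=\"%d\" name=\"Picture %d\"/>",
      "<xdr:cNvPicPr/></xdr:nvPicPr>",
      "<xdr:blipFill><a:blip r:embed=\"%s\"/><a:stretch><a:fillRect/></a:stretch></xdr:blipFill>",
      "<xdr:spPr><a:prstGeom prst=\"rect\"><a:avLst/></a:prstGeom></xdr:spPr></xdr:pic>"),
      i, i, rids[i])
    paste0("<xdr:oneCellAnchor>", from,
           "<xdr:ext cx=\"914400\" cy=\"914400\"/>", body,
           "<xdr:clientData/></xdr:oneCellAnchor>")
  }, character(1))
  paste0(
    XMLDECL,
    "<xdr:wsDr xmlns:xdr=\"http://schemas.openxmlformats.org/drawingml/2006/spreadsheetDrawing\"",
    " xmlns:a=\"http://schemas.openxmlformats.org/drawingml/2006/main\"",
    " xmlns:r=\"", NS_REL, "\">",
    paste(anchors, collapse = ""), "</xdr:wsDr>")
}

chart_stub_xml <- function() {
  paste0(
    XMLDECL,
    "<c:chartSpace xmlns:c=\"http://schemas.openxmlformats.org/drawingml/2006/chart\"",
    " xmlns:a=\"http://schemas.openxmlformats.org/drawingml/2006/main\"",
    " xmlns:r=\"", NS_REL, "\">",
    "<c:chart><c:plotArea><c:layout/>",
    "<c:barChart><c:barDir val=\"col\"/><c:grouping val=\"clustered\"/></c:barChart>",
    "</c:plotArea><c:plotVisOnly val=\"1\"/></c:chart></c:chartSpace>")
}

pivot_stub_xml <- function(row, col) {
  paste0(
    XMLDECL,
    "<pivotTableDefinition xmlns=\"", NS_MAIN, "\" name=\"PivotStub\" cacheId=\"0\">",
    "<location ref=\"", a1(row, col), "\" firstHeaderRow=\"1\" firstDataRow=\"1\" firstDataCol=\"1\"/>",
    "</pivotTableDefinition>")
}

rels_xml <- function(ids, types, targets) {
  paste0(
    XMLDECL, "<Relationships xmlns=\"", NS_PKGREL, "\">",
    paste0(sprintf("<Relationship Id=\"%s\" Type=\"%s\" Target=\"%s\"/>",
                   ids, types, targets), collapse = ""),
    "</Relationships>")
}

#' Write a workbook to an .xlsx file
#'
#' Serializes the in-memory model to Office Open XML SpreadsheetML. The
#' round-trip guarantee with [read_workbook()] covers cell values and kinds,
#' formulas (text plus cached value), comments, merged ranges, fill and font
#' colors, sheet order and document properties. Charts, pictures and pivot
#' tables are written as minimal stub parts carrying their anchor only.
#'
#' @param wb a `wb_workbook`.
#' @param path output path ending in `.xlsx`.
#' @return `path`, invisibly.
#' @export
write_workbook <- function(wb, path) {
  stopifnot(inherits(wb, "wb_workbook"))
  if (!grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    stop("write_workbook() writes .xlsx; use export_csv() for CSV output",
         call. = FALSE)
  }
  if (length(wb$sheets) == 0) stop("workbook has no sheets", call. = FALSE)
  stage <- file.path(tempfile("xlsxw"), "pkg")
  parts <- character()  # zip-relative paths written
  put <- function(rel, content) {
    full <- file.path(stage, rel)
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    if (is.raw(content)) writeBin(content, full)
    else writeLines(content, full, sep = "", useBytes = TRUE)
    parts <<- c(parts, rel)
  }

  styles <- build_styles(wb)
  n_sheet <- length(wb$sheets)
  overrides <- character()
  ct_override <- function(part, type) {
    overrides <<- c(overrides, sprintf(
      "<Override PartName=\"/%s\" ContentType=\"%s\"/>", part, type))
  }

  n_comments <- 0L; n_drawings <- 0L; n_charts <- 0L
  n_media <- 0L; n_pivots <- 0L
  for (k in seq_len(n_sheet)) {
    sh <- wb$sheets[[k]]
    rel_ids <- character(); rel_types <- character(); rel_targets <- character()
    # comments part
    if (any(!is.na(sh$cells$comment))) {
      n_comments <- n_comments + 1L
      part <- sprintf("xl/comments%d.xml", n_comments)
      put(part, comments_xml(sh$cells))
      ct_override(part, "application/vnd.openxmlformats-officedocument.spreadsheetml.comments+xml")
      rel_ids <- c(rel_ids, sprintf("rId%d", length(rel_ids) + 1L))
      rel_types <- c(rel_types, paste0(REL_T, "/comments"))
      rel_targets <- c(rel_targets, sprintf("../comments%d.xml", n_comments))
    }
    # drawing part (charts + pictures)
    drawable <- sh$objects[sh$objects$kind %in% c("chart", "picture"), , drop = FALSE]
    drawing_rid <- NA_character_
    if (nrow(drawable) > 0) {
      n_drawings <- n_drawings + 1L
      dpart <- sprintf("xl/drawings/drawing%d.xml", n_drawings)
      drids <- character(); dtypes <- character(); dtargets <- character()
      obj_rids <- character(nrow(drawable))
      for (i in seq_len(nrow(drawable))) {
        rid <- sprintf("rId%d", i)
        obj_rids[i] <- rid
        if (drawable$kind[i] == "chart") {
          n_charts <- n_charts + 1L
          cpart <- sprintf("xl/charts/chart%d.xml", n_charts)
          put(cpart, chart_stub_xml())
          ct_override(cpart, "application/vnd.openxmlformats-officedocument.drawingml.chart+xml")
          drids <- c(drids, rid)
          dtypes <- c(dtypes, paste0(REL_T, "/chart"))
          dtargets <- c(dtargets, sprintf("../charts/chart%d.xml", n_charts))
        } else {
          n_media <- n_media + 1L
          mpart <- sprintf("xl/media/image%d.png", n_media)
          put(mpart, png_stub())
          drids <- c(drids, rid)
          dtypes <- c(dtypes, paste0(REL_T, "/image"))
          dtargets <- c(dtargets, sprintf("../media/image%d.png", n_media))
        }
      }
      put(dpart, drawing_xml(drawable, obj_rids))
      ct_override(dpart, "application/vnd.openxmlformats-officedocument.drawing+xml")
      put(sprintf("xl/drawings/_rels/drawing%d.xml.rels", n_drawings),
          rels_xml(drids, dtypes, dtargets))
      drawing_rid <- sprintf("rId%d", length(rel_ids) + 1L)
      rel_ids <- c(rel_ids, drawing_rid)
      rel_types <- c(rel_types, paste0(REL_T, "/drawing"))
      rel_targets <- c(rel_targets, sprintf("../drawings/drawing%d.xml", n_drawings))
    }
    # pivot-table stubs
    pivots <- sh$objects[sh$objects$kind == "pivot_table", , drop = FALSE]
    for (i in seq_len(nrow(pivots))) {
      n_pivots <- n_pivots + 1L
      ppart <- sprintf("xl/pivotTables/pivotTable%d.xml", n_pivots)
      put(ppart, pivot_stub_xml(pivots$row[i], pivots$col[i]))
      ct_override(ppart, "application/vnd.openxmlformats-officedocument.spreadsheetml.pivotTable+xml")
      rel_ids <- c(rel_ids, sprintf("rId%d", length(rel_ids) + 1L))
      rel_types <- c(rel_types, paste0(REL_T, "/pivotTable"))
      rel_targets <- c(rel_targets, sprintf("../pivotTables/pivotTable%d.xml", n_pivots))
    }
    spart <- sprintf("xl/worksheets/sheet%d.xml", k)
    put(spart, sheet_xml(sh, styles$lookup, !is.na(drawing_rid), drawing_rid))
    ct_override(spart, "application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml")
    if (length(rel_ids) > 0) {
      put(sprintf("xl/worksheets/_rels/sheet%d.xml.rels", k),
          rels_xml(rel_ids, rel_types, rel_targets))
    }
  }

  put("xl/styles.xml", styles$xml)
  ct_override("xl/styles.xml", "application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml")

  sheet_entries <- vapply(seq_len(n_sheet), function(k) sprintf(
    "<sheet name=\"%s\" sheetId=\"%d\" r:id=\"rId%d\"/>",
    xml_escape(wb$sheets[[k]]$name), k, k), character(1))
  put("xl/workbook.xml", paste0(
    XMLDECL, "<workbook xmlns=\"", NS_MAIN, "\" xmlns:r=\"", NS_REL, "\">",
    "<sheets>", paste(sheet_entries, collapse = ""), "</sheets></workbook>"))
  ct_override("xl/workbook.xml", "application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml")
  put("xl/_rels/workbook.xml.rels", rels_xml(
    c(sprintf("rId%d", seq_len(n_sheet)), sprintf("rId%d", n_sheet + 1L)),
    c(rep(paste0(REL_T, "/worksheet"), n_sheet), paste0(REL_T, "/styles")),
    c(sprintf("worksheets/sheet%d.xml", seq_len(n_sheet)), "styles.xml")))

  dp <- wb$doc_properties
  put("docProps/core.xml", paste0(
    XMLDECL,
    "<cp:coreProperties xmlns:cp=\"http://schemas.openxmlformats.org/package/2006/metadata/core-properties\"",
    " xmlns:dc=\"http://purl.org/dc/elements/1.1/\"",
    " xmlns:dcterms=\"http://purl.org/dc/terms/\"",
    " xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\">",
    "<dc:creator>", xml_escape(dp$author %||% ""), "</dc:creator>",
    "<dc:title>", xml_escape(dp$title %||% ""), "</dc:title>",
    "<dcterms:created xsi:type=\"dcterms:W3CDTF\">",
    xml_escape(dp$created %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    "</dcterms:created></cp:coreProperties>"))
  ct_override("docProps/core.xml", "application/vnd.openxmlformats-package.core-properties+xml")

  put("_rels/.rels", rels_xml(
    c("rId1", "rId2"),
    c(paste0(REL_T, "/officeDocument"),
      "http://schemas.openxmlformats.org/package/2006/relationships/metadata/core-properties"),
    c("xl/workbook.xml", "docProps/core.xml")))

  put("[Content_Types].xml", paste0(
    XMLDECL,
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Default Extension=\"png\" ContentType=\"image/png\"/>",
    paste(overrides, collapse = ""), "</Types>"))

  path <- normalizePath(path, mustWork = FALSE)
  ok <- tryCatch({
    zip::zip(path, files = parts, root = stage, mode = "mirror")
    TRUE
  }, error = function(e) {
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  unlink(dirname(stage), recursive = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
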