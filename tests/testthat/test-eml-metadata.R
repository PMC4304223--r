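test_that("the schema has 47 elements with exactly 7 required", {
  s <- schema_elements()
  expect_identical(nrow(s), 47L)
  expect_identical(sum(s$required), 7L)
  expect_setequal(s$name[s$required],
                  c("Today's date", "Title of dataset", "Abstract",
                    "Keyword(s)", "Creator: First name", "Creator: Last name",
                    "Creator: Email"))
  expect_true("Creator: Email" %in% s$name[s$required])
  expect_identical(anyDuplicated(s$id), 0L)
  # group sizes mirror the published table: 7 basic + 20 personnel +
  # 15 dataset file-level elements, plus 5 attribute-level
  expect_identical(
    as.vector(table(s$group)[c("basic", "personnel", "dataset", "attribute")]),
    c(7L, 20L, 15L, 5L))
})

test_that("completeness is exactly the 7-required predicate", {
  md <- minimal_metadata()
  expect_true(is_complete(md))
  expect_identical(nrow(validate_metadata(md)), 0L)
  # dropping any single required element flips completeness off
  for (id in required_ids()) {
    fl <- md$file_level
    fl[[id]] <- NULL
    expect_false(is_complete(new_metadata(fl)), label = paste("without", id))
  }
  # optional elements do not gate
  md2 <- set_elements(md, publisher = "Some Repository")
  expect_true(is_complete(md2))
})

test_that("validation reports missing required elements and invariants", {
  md <- set_elements(minimal_metadata(), abstract = NULL)
  f <- validate_metadata(md)
  expect_identical(nrow(f), 1L)
  expect_identical(f$element, "Abstract")

  bad <- set_elements(minimal_metadata(),
                      south_bounding = "50", north_bounding = "40",
                      creator_email = "not-an-email",
                      temporal_begin = "01/02/2011",
                      west_bounding = "-200")
  f2 <- validate_metadata(bad)
  expect_true("South bounding coordinate" %in% f2$element)
  expect_true(any(grepl("email", f2$problem)))
  expect_true(any(grepl("ISO 8601", f2$problem)))
  expect_true(any(grepl("longitude", f2$problem)))
})

test_that("prepopulate seeds date, creator names and title", {
  wb <- new_workbook(list(set_cell(new_sheet("d"), 1, 1, 1)),
                     doc_properties = list(author = "Rosa Delgado",
                                           title = "Kelp biomass"))
  md <- prepopulate(wb)
  expect_identical(md$file_level$creator_first_name, "Rosa")
  expect_identical(md$file_level$creator_last_name, "Delgado")
  expect_identical(md$file_level$title, "Kelp biomass")
  expect_identical(md$file_level$today_date, format(Sys.Date(), "%Y-%m-%d"))

  # multi-word given names split at the last whitespace
  wb2 <- new_workbook(list(new_sheet("d")),
                      doc_properties = list(author = "Mary Jo van Dam"))
  md2 <- prepopulate(wb2)
  expect_identical(md2$file_level$creator_first_name, "Mary Jo van")
  expect_identical(md2$file_level$creator_last_name, "Dam")

  # no author: names stay empty; no title: source file stem is used
  wb3 <- new_workbook(list(new_sheet("d")),
                      source_path = "/tmp/stream_temps.xlsx")
  md3 <- prepopulate(wb3)
  expect_null(md3$file_level$creator_first_name)
  expect_identical(md3$file_level$title, "stream_temps")
})

test_that("attribute stubs come from the header row in column order", {
  sh <- sheet_from_rows(list(list("site", "date", "temp"),
                             list("A", 1, 2), list("B", 3, 4)))
  region <- detect_regions(sh)[[1]]
  at <- attributes_from_header(region, sh)
  expect_identical(at$parameter_name, c("site", "date", "temp"))
  expect_identical(at$column_index, 1:3)
  expect_identical(at$description, rep("", 3))

  one_col <- sheet_from_rows(list(list("only"), list(1)))
  expect_identical(nrow(attributes_from_header(
    detect_regions(one_col)[[1]], one_col)), 1L)

  headerless <- sheet_from_rows(list(list(1, 2), list(3, 4)))
  expect_error(attributes_from_header(
    detect_regions(headerless)[[1]], headerless), "header row")
})

test_that("EML serialization round-trips every populated field", {
  md <- full_metadata()
  expect_identical(nrow(validate_metadata(md)), 0L)
  eml <- to_eml(md)
  # independent parse of a few fields with xml2 directly
  doc <- xml2::read_xml(eml)
  expect_identical(
    xml2::xml_text(xml2::xml_find_first(doc, "//*[local-name()='title']")),
    md$file_level$title)
  expect_identical(
    xml2::xml_text(xml2::xml_find_first(
      doc, "//*[local-name()='electronicMailAddress']")),
    "ana@example.org")
  expect_length(
    xml2::xml_find_all(doc, "//*[local-name()='attribute']"), 3)
  # full field-by-field recovery
  back <- from_eml(eml)
  expect_identical(back$file_level, md$file_level)
  expect_identical(back$attributes, md$attributes)

  # minimal 7-field record parses and recovers the title
  mini <- minimal_metadata()
  back2 <- from_eml(to_eml(mini))
  expect_identical(back2$file_level, mini$file_level)

  # incomplete record refuses to serialize, listing findings
  expect_error(to_eml(set_elements(mini, title = NULL)), "Title of dataset")
})

test_that("the Metadata sheet embeds and extracts the record", {
  wb <- generate_fixture()
  md <- full_metadata()
  wb2 <- embed_metadata_sheet(wb, md)
  expect_identical(sheet_names(wb2), c("data", "notes", "Metadata")[c(1, 3)])
  back <- extract_metadata_sheet(wb2)
  expect_identical(back$file_level, md$file_level)
  expect_identical(back$attributes, md$attributes)
  # embed -> extract -> to_eml equals to_eml directly
  expect_identical(to_eml(back), to_eml(md))
  # data sheets untouched
  expect_identical(wb2$sheets[[1]], wb$sheets[[1]])
  # re-embedding replaces, never duplicates
  wb3 <- embed_metadata_sheet(wb2, minimal_metadata())
  expect_identical(sum(sheet_names(wb3) == "Metadata"), 1L)
  expect_identical(extract_metadata_sheet(wb3)$file_level,
                   minimal_metadata()$file_level)
  # the Metadata tab survives an xlsx save/reopen cycle
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(wb2, path)
  expect_identical(extract_metadata_sheet(read_workbook(path))$file_level,
                   md$file_level)
  expect_error(extract_metadata_sheet(wb), "no 'Metadata' sheet")
})

test_that("metadata entry files round-trip through the documented format", {
  md <- full_metadata()
  path <- withr::local_tempfile(fileext = ".txt")
  write_metadata_file(md, path)
  back <- read_metadata_file(path)
  expect_identical(back$file_level, md$file_level)
  expect_identical(back$attributes, md$attributes)
  expect_error(read_metadata_file(withr::local_tempfile()), "not found")
  bad <- withr::local_tempfile()
  writeLines(c("nonsense line without colon"), bad)
  expect_error(read_metadata_file(bad), "cannot parse")
})
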