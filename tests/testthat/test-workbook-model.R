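test_that("A1 rendering is bijective with (row, column)", {
  expect_identical(a1(3, 2), "B3")
  expect_identical(col_letter(c(1, 26, 27, 52, 703)),
                   c("A", "Z", "AA", "AZ", "AAA"))
  set.seed(42)
  rows <- sample.int(10000, 200)
  cols <- sample.int(800, 200)
  back <- parse_a1(a1(rows, cols))
  expect_identical(back$row, as.integer(rows))
  expect_identical(back$col, as.integer(cols))
  expect_error(parse_a1("3B"), "A1")
})

test_that("value_kind_of classifies scalars totally and deterministically", {
  expect_identical(value_kind_of("3.14"), "number")
  expect_identical(value_kind_of("-2e-3"), "number")
  expect_identical(value_kind_of(""), "empty")
  expect_identical(value_kind_of(NULL), "empty")
  expect_identical(value_kind_of(NA_character_), "empty")
  # ISO-8601 oracle: the date strings are exactly those base R parses
  # strictly as %Y-%m-%d
  candidates <- c("2011-08-01", "2011-13-01", "2011-08-41", "11-08-01",
                  "2011/08/01", "2011-08-01T10:00:00")
  oracle <- vapply(candidates, function(s) {
    grepl("^\\d{4}-\\d{2}-\\d{2}$", s) &&
      !is.na(suppressWarnings(as.Date(s, "%Y-%m-%d")))
  }, logical(1))
  got <- vapply(candidates, value_kind_of, character(1)) == "date"
  expect_identical(unname(got), unname(oracle))
  expect_identical(value_kind_of("n/a"), "text")
  expect_identical(value_kind_of("1,2"), "text")
  expect_identical(value_kind_of(TRUE), "boolean")
  expect_identical(value_kind_of(as.Date("2020-01-01")), "date")
  # deterministic: repeated calls agree
  expect_identical(value_kind_of("7e2"), value_kind_of("7e2"))
})

test_that("cell and sheet operations behave functionally", {
  sh <- new_sheet("s")
  sh2 <- set_cell(sh, 2, 3, 1.5)
  expect_null(get_cell(sh, 2, 3))  # original untouched
  expect_identical(get_cell(sh2, 2, 3)$kind, "number")
  sh2 <- set_cell(sh2, 2, 3, comment = "note")
  expect_identical(get_cell(sh2, 2, 3)$value, 1.5)
  expect_identical(get_cell(sh2, 2, 3)$comment, "note")
  sh2 <- clear_cell(sh2, 2, 3)
  expect_null(get_cell(sh2, 2, 3))
  expect_error(merge_cells(merge_cells(sh, "B2:C3"), "C3:D4"), "overlap")
  expect_error(new_workbook(list(new_sheet("a"), new_sheet("a"))), "unique")
})

test_that("used_range is the minimal rectangle over non-empty cells", {
  sh <- new_sheet("s")
  expect_null(used_range(sh))
  sh <- set_cell(sh, 3, 2, "x")
  sh <- set_cell(sh, 7, 5, 1)
  sh <- set_cell(sh, 10, 9, comment = "annotation only")
  ur <- used_range(sh)
  expect_identical(ur, list(top = 3L, left = 2L, bottom = 7L, right = 5L))
  expect_identical(used_range(sh, values_only = FALSE)$bottom, 10L)
})

test_that("xlsx write -> read round-trips the supported feature set", {
  sh <- new_sheet("Data")
  sh <- set_cell(sh, 1, 1, "label")
  sh <- set_cell(sh, 1, 2, "x < 3 & y > \"2\"")  # escaping
  sh <- set_cell(sh, 2, 1, 3.14159)
  sh <- set_cell(sh, 2, 2, as.Date("2011-08-01"))
  sh <- set_cell(sh, 3, 1, TRUE)
  sh <- set_cell(sh, 3, 2, "007", as_text = TRUE)  # text that looks numeric
  sh <- set_cell(sh, 4, 1, 6, formula = "A2*2")
  sh <- set_cell(sh, 4, 2, fill = "00FF00", font_color = "0000FF")
  sh <- set_cell(sh, 5, 5, comment = "comment on an empty cell")
  sh <- merge_cells(sh, "B6:C7")
  sh <- add_object(sh, "chart", 2, 6)
  sh <- add_object(sh, "picture", 9, 1)
  sh <- add_object(sh, "pivot_table", 11, 3)
  sh2 <- new_sheet("Notes")
  sh2 <- set_cell(sh2, 1, 1, "second sheet")
  wb <- new_workbook(list(sh, sh2),
                     doc_properties = list(author = "Ana Mendez",
                                           title = "survey"))
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(wb, path)
  got <- read_workbook(path)
  expect_wb_equal(got, wb)
  expect_identical(got$doc_properties$author, "Ana Mendez")
  expect_identical(got$doc_properties$title, "survey")
  expect_identical(got$source_format, "xlsx")
  # fixture with a known comment, re-read (independent of expect_wb_equal)
  expect_identical(get_cell(got$sheets[[1]], 5, 5)$comment,
                   "comment on an empty cell")
})

test_that("3-sheet order and merged ranges survive the round-trip", {
  mk <- function(nm, v) set_cell(new_sheet(nm), 1, 1, v)
  wb <- new_workbook(list(mk("c", 1), mk("a", 2), mk("b", 3)))
  wb$sheets[[2]] <- merge_cells(wb$sheets[[2]], "B2:C3")
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(wb, path)
  got <- read_workbook(path)
  expect_identical(sheet_names(got), c("c", "a", "b"))
  expect_identical(got$sheets[[2]]$merged, "B2:C3")
})

test_that("CSV reading sniffs cell kinds", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  wb <- read_workbook(path)
  expect_length(wb$sheets, 1)
  expect_identical(wb$sheets[[1]]$name, sub("\\.csv$", "", basename(path)))
  expect_identical(get_cell(wb$sheets[[1]], 1, 1),
                   list(value = "a", kind = "text", formula = NA_character_,
                        comment = NA_character_, fill = NA_character_,
                        font_color = NA_character_))
  expect_identical(get_cell(wb$sheets[[1]], 2, 2)$value, 2)
  expect_identical(wb$source_format, "csv")
})

test_that("CSV reading honors RFC 4180 quoting and sniffs dates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('site,when,note', '"Oakland, CA",2011-08-01,"say ""hi"""'),
             path)
  wb <- read_workbook(path)
  sh <- wb$sheets[[1]]
  expect_identical(get_cell(sh, 2, 1)$value, "Oakland, CA")
  expect_identical(get_cell(sh, 2, 2)$kind, "date")
  expect_identical(get_cell(sh, 2, 2)$value, as.Date("2011-08-01"))
  expect_identical(get_cell(sh, 2, 3)$value, 'say "hi"')
})

test_that("read/write errors are informative", {
  expect_error(read_workbook("no-such-file.xlsx"), "not found")
  bad <- withr::local_tempfile(fileext = ".xlsx")
  writeLines("this is not a zip archive", bad)
  expect_error(read_workbook(bad), "not a readable .xlsx")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", txt)
  expect_error(read_workbook(txt), "unsupported file extension")
  wb <- wb1(set_cell(new_sheet("s"), 1, 1, 1))
  expect_error(write_workbook(wb, withr::local_tempfile(fileext = ".csv")),
               "export_csv")
  expect_error(
    write_workbook(wb, file.path(tempfile("missingdir"), "x", "y.xlsx")),
    "cannot write")
})
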