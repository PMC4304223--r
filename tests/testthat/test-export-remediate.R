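test_that("export writes one CSV per non-empty sheet with stated names", {
  mk <- function(nm) sheet_from_rows(list(list("a", "b"), list(1, 2)), nm)
  wb <- new_workbook(list(mk("one"), mk("two"), new_sheet("blank"), mk("th ree")))
  out <- withr::local_tempdir()
  files <- export_csv(wb, out, stem = "survey")
  expect_length(files, 3)
  expect_identical(basename(files),
                   c("survey_one.csv", "survey_two.csv", "survey_th_ree.csv"))
  # single sheet: just <stem>.csv
  single <- export_csv(new_workbook(list(mk("only"))), out, stem = "solo")
  expect_identical(basename(single), "solo.csv")
  # name collisions are suffixed
  coll <- new_workbook(list(mk("a b"), mk("a-b"), mk("a_b")))
  files3 <- basename(export_csv(coll, out, stem = "c"))
  expect_identical(files3, c("c_a_b.csv", "c_a-b.csv", "c_a_b_2.csv"))
  expect_error(export_csv(new_workbook(list(new_sheet("x"))), out),
               "nothing to export")
})

test_that("CSV serialization follows RFC 4180 and round-trips values", {
  sh <- new_sheet("rt")
  sh <- set_cell(sh, 1, 1, "a,b")
  sh <- set_cell(sh, 1, 2, "say \"hi\"")
  sh <- set_cell(sh, 2, 1, 1 / 3)
  sh <- set_cell(sh, 2, 2, as.Date("2011-08-01"))
  sh <- set_cell(sh, 3, 1, 1e-9)
  sh <- set_cell(sh, 3, 2, 123456.789)
  out <- withr::local_tempdir()
  f <- export_csv(new_workbook(list(sh)), out, stem = "rt")
  lines <- readLines(f)
  expect_identical(lines[1], "\"a,b\",\"say \"\"hi\"\"\"")
  back <- read_workbook(f)$sheets[[1]]
  for (i in seq_len(nrow(sh$cells))) {
    r <- sh$cells$row[i]; cc <- sh$cells$col[i]
    expect_identical(get_cell(back, r, cc)$value, get_cell(sh, r, cc)$value,
                     label = paste("cell", a1(r, cc)))
  }
})

test_that("line endings and merged-range semantics are honored", {
  sh <- sheet_from_rows(list(list("a", "b"), list(1, 2)))
  sh <- merge_cells(sh, "A1:B1")
  out <- withr::local_tempdir()
  f <- export_csv(new_workbook(list(sh)), out, stem = "m",
                  line_ending = "crlf")
  raw <- readChar(f, file.size(f), useBytes = TRUE)
  expect_match(raw, "\r\n", fixed = TRUE)
  # anchor value at top-left, empty elsewhere in the merged range
  expect_identical(readLines(f)[1], "a,b")  # b holds its own value here
  sh2 <- new_sheet("m2")
  sh2 <- set_cell(sh2, 1, 1, "site")
  sh2 <- merge_cells(sh2, "A1:B1")
  sh2 <- set_cell(sh2, 2, 1, 1); sh2 <- set_cell(sh2, 2, 2, 2)
  f2 <- export_csv(new_workbook(list(sh2)), out, stem = "m2")
  expect_identical(readLines(f2)[1], "site,")
})

test_that("comments_to_column relocates comments into a Comments column", {
  wb <- wb1(sheet_from_rows(list(list("a", "b"), list(1, 2), list(3, 4))))
  expect_identical(comments_to_column(wb)$sheets[[1]]$cells,
                   wb$sheets[[1]]$cells)

  sh <- sheet_from_rows(list(list("a", "b"), list(1, 2), list(3, 4)))
  sh <- set_cell(sh, 3, 1, comment = "left note")
  sh <- set_cell(sh, 3, 2, comment = "right note")
  sh <- set_cell(sh, 2, 2, comment = "solo")
  fixed <- comments_to_column(wb1(sh))$sheets[[1]]
  expect_identical(get_cell(fixed, 1, 3)$value, "Comments")
  expect_identical(get_cell(fixed, 2, 3)$value, "solo")
  # two comments on one row join in column order with "; "
  expect_identical(get_cell(fixed, 3, 3)$value, "left note; right note")
  expect_false(any(!is.na(fixed$cells$comment)))
})

test_that("strip and unmerge transforms are idempotent and information-preserving", {
  sh <- sheet_from_rows(list(list("a", "b"), list(1, 2)))
  sh <- set_cell(sh, 2, 1, fill = "FF0000", font_color = "00FF00")
  sh <- add_object(sh, "picture", 5, 5)
  sh <- set_cell(sh, 6, 1, "site")
  sh <- merge_cells(sh, "A6:B7")
  wb <- wb1(sh)

  once <- strip_formatting(wb)
  expect_identical(strip_formatting(once), once)
  expect_false(any(!is.na(once$sheets[[1]]$cells$fill)))

  noobj <- strip_objects(wb)
  expect_identical(strip_objects(noobj), noobj)
  expect_identical(nrow(noobj$sheets[[1]]$objects), 0L)

  unm <- unmerge_fill(wb)
  expect_identical(unmerge_fill(unm), unm)
  expect_length(unm$sheets[[1]]$merged, 0)
  # B2:C3-style fill: all four cells carry the anchor value
  for (r in 6:7) for (cc in 1:2) {
    expect_identical(get_cell(unm$sheets[[1]], r, cc)$value, "site")
  }
})

test_that("applying every auto-fix silences the four fixable rules", {
  wb <- generate_fixture(c("embedded_objects", "embedded_comments",
                           "color_coding", "merged_cells"), seed = 11)
  report <- run_all_checks(remediate_all(wb))
  expect_identical(
    unname(report$per_rule_counts[c("embedded_objects", "embedded_comments",
                                    "color_coding", "merged_cells")]),
    rep(0L, 4))
})
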