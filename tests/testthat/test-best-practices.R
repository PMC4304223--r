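test_that("the rule catalogue holds the 11 rules in printed order", {
  cat_df <- rule_catalogue()
  expect_identical(nrow(cat_df), 11L)
  expect_identical(cat_df$rule_id, c(
    "embedded_objects", "embedded_comments", "commas", "special_characters",
    "color_coding", "mixed_types", "non_contiguous", "merged_cells",
    "blank_cells", "header_problem", "multiple_sheets"))
  expect_match(cat_df$why[2],
               "Comments will not be visible when data are exported",
               fixed = TRUE)
  expect_match(cat_df$remedy[11], "export the data as separate .csv files",
               fixed = TRUE)
  expect_match(cat_df$remedy[3],
               "Split pieces of information into multiple columns",
               fixed = TRUE)
  expect_identical(cat_df$severity,
                   c(rep("warning", 10), "info"))
})

test_that("embedded object and comment checks are global and located", {
  sh <- sheet_from_rows(list(list("a", "b"), list(1, 2)))
  expect_length(check_embedded_objects(wb1(sh)), 0)
  sh_chart <- add_object(sh, "chart", 5, 5)
  issues <- check_embedded_objects(wb1(sh_chart))
  expect_length(issues, 1)
  expect_identical(issues[[1]]$locations, "E5")
  # chart + picture on different sheets -> 2 issues (one per sheet)
  sh_b <- add_object(set_cell(new_sheet("t2"), 1, 1, 1), "picture", 2, 2)
  issues2 <- check_embedded_objects(new_workbook(list(sh_chart, sh_b)))
  expect_length(issues2, 2)

  # comments: one issue aggregating locations; empty commented cell counts
  sh_c <- set_cell(sh, 2, 2, comment = "c1")
  sh_c <- set_cell(sh_c, 7, 4, comment = "on an empty cell")
  ci <- check_embedded_comments(wb1(sh_c))
  expect_length(ci, 1)
  expect_setequal(ci[[1]]$locations, c("B2", "D7"))
  expect_true(ci[[1]]$auto_fixable)
})

test_that("comma and special-character checks scope to table regions", {
  sh <- sheet_from_rows(list(
    list("city", "n"),
    list("Oakland, CA", 3),
    list("Davis", 4)))
  issues <- check_commas(wb1(sh))
  locs <- unlist(lapply(issues, `[[`, "locations"))
  expect_identical(locs, "A2")
  # region maximality means every valued cell lies in some region; scoping
  # therefore only exempts annotation-bearing empty cells (tested below)

  # cell with comment only (no value) holding no text: not flagged
  sh2 <- sheet_from_rows(list(list("a"), list(1)))
  sh2 <- set_cell(sh2, 1, 5, comment = "note, with comma")
  expect_length(check_commas(wb1(sh2)), 0)

  # "1,2" typed as the number 12 is not a text cell
  sh3 <- sheet_from_rows(list(list("a"), list(12)))
  expect_length(check_commas(wb1(sh3)), 0)

  # special characters: oracle = allowed-set membership
  allowed <- c(LETTERS, letters, 0:9, " ", ".", "_", "-", "(", ")", "/")
  values <- c("µg/L", "site_01", "α=0.05", "a(b)/c.d-e", "x;y")
  oracle_bad <- vapply(values, function(v) {
    chars <- strsplit(v, "")[[1]]
    any(!chars %in% allowed)
  }, logical(1))
  sh4 <- new_sheet("s")
  sh4 <- set_cell(sh4, 1, 1, "v")
  for (i in seq_along(values)) sh4 <- set_cell(sh4, 1 + i, 1, values[i])
  issues4 <- check_special_characters(wb1(sh4))
  flagged <- unlist(lapply(issues4, `[[`, "locations"))
  expect_setequal(flagged, a1(1 + which(oracle_bad), 1))
  # a comma alone never fires the special-character rule
  sh5 <- sheet_from_rows(list(list("a"), list("x, y")))
  expect_length(check_special_characters(wb1(sh5)), 0)
  expect_length(check_commas(wb1(sh5)), 1)
})

test_that("color coding is flagged inside regions only", {
  sh <- sheet_from_rows(list(list("a", "b"), list(1, 2), list(3, 4)))
  expect_length(check_color_coding(wb1(sh)), 0)
  sh <- set_cell(sh, 2, 1, fill = "FFFF00")
  sh <- set_cell(sh, 2, 2, fill = "FFFF00")
  sh <- set_cell(sh, 3, 1, font_color = "FF0000")
  sh <- set_cell(sh, 9, 9, fill = "00FF00")  # empty cell far away: no region
  issues <- check_color_coding(wb1(sh))
  expect_length(issues, 1)
  expect_setequal(issues[[1]]$locations, c("A2", "B2", "A3"))
})

test_that("mixed-type detection partitions kinds below the header", {
  # kind-partition oracle on a constructed column
  sh <- sheet_from_rows(list(
    list("site", "temp", "flag"),
    list("A", 12.5, 1),
    list("B", "n/a", 2),
    list("C", 13.1, 3)))
  issues <- check_mixed_types(wb1(sh))
  expect_length(issues, 1)
  expect_identical(issues[[1]]$locations, "B2:B4")
  expect_identical(issues[[1]]$detail, "number+text")
  # all-number column clean; text header over numbers clean (header excluded)
  sh2 <- sheet_from_rows(list(list("a", "b"), list(1, 2), list(3, 4)))
  expect_length(check_mixed_types(wb1(sh2)), 0)
  # headerless table: first row participates
  sh3 <- sheet_from_rows(list(list(1, "x"), list(2, 3)))
  issues3 <- check_mixed_types(wb1(sh3))
  expect_length(issues3, 1)
  expect_identical(issues3[[1]]$locations, "B1:B2")
})

test_that("non-contiguous data yields one issue per offending sheet", {
  one <- sheet_from_rows(list(list("a"), list(1)))
  expect_length(check_non_contiguous(wb1(one)), 0)
  three <- sheet_from_rows(list(
    list("a", NA, "b", NA, "c"),
    list(1, NA, 2, NA, 3)))
  other <- sheet_from_rows(list(list("z"), list(9)), name = "t2")
  issues <- check_non_contiguous(new_workbook(list(three, other)))
  expect_length(issues, 1)
  expect_identical(issues[[1]]$sheet, "s")
  expect_length(issues[[1]]$locations, 3)
})

test_that("merged ranges and interior blanks are flagged", {
  sh <- sheet_from_rows(list(list("a", "b"), list(1, 2)))
  expect_length(check_merged_cells(wb1(sh)), 0)
  shm <- merge_cells(merge_cells(sh, "E1:F2"), "E4:E5")
  im <- check_merged_cells(wb1(shm))
  expect_length(im, 1)
  expect_setequal(im[[1]]$locations, c("E1:F2", "E4:E5"))

  # a 5x4 region with one hole at C3
  rows <- c(list(list("w", "x", "y", "z")),
            lapply(1:4, function(i) as.list(as.numeric(1:4 * i))))
  sh2 <- sheet_from_rows(rows)
  sh2 <- clear_cell(sh2, 3, 3)
  ib <- check_blank_cells(wb1(sh2))
  expect_length(ib, 1)
  expect_identical(ib[[1]]$locations, "C3")
  # separator rows are never inside a region
  sep <- sheet_from_rows(list(list("a"), list(1), list(NA), list("b"), list(2)))
  issues <- check_blank_cells(wb1(sep))
  expect_length(issues, 0)
})

test_that("header problems distinguish absent, multiple and duplicate", {
  ok <- sheet_from_rows(list(list("a", "b"), list(1, 2)))
  expect_length(check_header(wb1(ok)), 0)
  absent <- sheet_from_rows(list(list(1, 2), list(3, 4)))
  ia <- check_header(wb1(absent))
  expect_length(ia, 1)
  expect_identical(ia[[1]]$detail, "absent")
  multiple <- sheet_from_rows(list(
    list("a", "b"), list("x", "y"), list(1, 2)))
  im <- check_header(wb1(multiple))
  expect_identical(im[[1]]$detail, "multiple")
  expect_identical(im[[1]]$locations, "A1:B2")
  dup <- sheet_from_rows(list(list("a", "a"), list(1, 2)))
  idup <- check_header(wb1(dup))
  expect_identical(idup[[1]]$detail, "duplicate")
  expect_match(idup[[1]]$remedy, "unique parameter names")
})

test_that("multiple sheets counts only non-empty sheets", {
  s1 <- sheet_from_rows(list(list("a"), list(1)))
  expect_length(check_multiple_sheets(wb1(s1)), 0)
  s2 <- sheet_from_rows(list(list("b"), list(2)), name = "t2")
  s3 <- new_sheet("blank")
  expect_length(check_multiple_sheets(new_workbook(list(s1, s3))), 0)
  issues <- check_multiple_sheets(new_workbook(list(s1, s2, s3)))
  expect_length(issues, 1)
  expect_setequal(issues[[1]]$locations, c("s", "t2"))
  expect_identical(issues[[1]]$severity, "info")
})

test_that("run_all_checks is deterministic and monotone under added defects", {
  wb <- generate_fixture(c("commas", "merged_cells"), seed = 5)
  r1 <- run_all_checks(wb)
  r2 <- run_all_checks(wb)
  r1$checked_at <- r2$checked_at <- NULL
  expect_identical(r1, r2)
  expect_identical(sum(r1$per_rule_counts), length(r1$issues))

  # monotonicity: every rule that fires for a defect set still fires with one
  # more defect added
  base_sets <- list(c("commas"), c("blank_cells", "color_coding"))
  for (base in base_sets) {
    fired <- names(which(run_all_checks(
      generate_fixture(base, seed = 2))$per_rule_counts > 0))
    for (extra in setdiff(rule_ids(), base)) {
      more <- run_all_checks(generate_fixture(c(base, extra), seed = 2))
      expect_true(all(fired %in% names(which(more$per_rule_counts > 0))),
                  label = paste("monotone adding", extra))
    }
  }
})

test_that("reports render as text and round-trip through JSON", {
  clean <- run_all_checks(generate_fixture())
  expect_match(render_report(clean, "text"), "0 issues", fixed = TRUE)
  expect_true(clean$passed)

  report <- run_all_checks(generate_fixture(c("commas", "mixed_types")))
  txt <- render_report(report, "text")
  expect_match(txt, "Split pieces of information into multiple columns",
               fixed = TRUE)
  expect_match(txt, "Why: ", fixed = TRUE)
  back <- parse_report(render_report(report, "json"))
  expect_identical(back$issues, report$issues)
  expect_identical(back$per_rule_counts, report$per_rule_counts)
  expect_identical(back$passed, report$passed)
  expect_error(render_report(report, "yaml"), "unknown report format")
})
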