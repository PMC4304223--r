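make_citation <- function(md = minimal_metadata(), ark = NULL) {
  build_citation(md, 2013, identifier = ark)
}

test_that("readiness gates on check-run, complete metadata and citation", {
  md <- minimal_metadata()
  report <- run_all_checks(generate_fixture())
  cit <- make_citation(md)

  ready <- assess_readiness(report, md, cit)
  expect_true(ready$ready)
  expect_false(assess_readiness(NULL, md, cit)$ready)
  expect_false(assess_readiness(report, md, NULL)$ready)
  expect_false(assess_readiness(report, set_elements(md, abstract = NULL),
                                cit)$ready)

  # a failed check does not gate: the check must have been run, not passed
  failing <- run_all_checks(generate_fixture("commas"))
  r <- assess_readiness(failing, md, cit)
  expect_true(r$ready)
  expect_false(r$compatibility_passed)

  # monotone: adding a gate never turns readiness off
  partial <- assess_readiness(NULL, md, cit)
  fuller <- assess_readiness(report, md, cit)
  expect_true(fuller$ready >= partial$ready)
})

test_that("build_package assembles a verifiable BagIt-style package", {
  wb <- generate_fixture("multiple_sheets")  # 2 non-empty sheets
  report <- run_all_checks(wb)
  cit <- make_citation()
  out <- file.path(withr::local_tempdir(), "pkg")
  pkg <- build_package(wb, cit$metadata, cit, out, report = report)

  csvs <- list.files(file.path(out, "data"))
  expect_length(csvs, 2)
  expect_true(all(c("eml.xml", "citation.ris", "citation.bib", "citation.xml",
                    "manifest-sha256.txt", "techmd.json") %in%
                  list.files(out)))
  expect_true(isTRUE(verify_manifest(out)))
  tech <- jsonlite::fromJSON(file.path(out, "techmd.json"))
  expect_identical(tech$total_files, length(pkg$files))
  expect_identical(tech$total_bytes, sum(tech$files$size))
  # independent checksum oracle for one file
  expect_identical(tech$files$sha256[tech$files$name == "eml.xml"],
                   digest::digest(file = file.path(out, "eml.xml"),
                                  algo = "sha256"))

  # tampering one byte breaks verification
  target <- file.path(out, "eml.xml")
  bytes <- readBin(target, "raw", file.size(target))
  bytes[100] <- as.raw(bitwXor(as.integer(bytes[100]), 1L))
  writeBin(bytes, target)
  v <- verify_manifest(out)
  expect_false(isTRUE(v))
  expect_true("eml.xml" %in% attr(v, "failures"))
})

test_that("build_package refuses an unready dataset, naming the gates", {
  wb <- generate_fixture()
  cit <- make_citation()
  out <- file.path(withr::local_tempdir(), "p2")
  expect_error(build_package(wb, cit$metadata, cit, out, report = NULL),
               "compatibility check not run")
  incomplete <- new_metadata(list(title = "t"))
  expect_error(
    build_package(wb, incomplete, NULL, out,
                  report = run_all_checks(wb)),
    "metadata incomplete; citation not generated")
})

test_that("filesystem deposit stores under the identifier and re-verifies", {
  wb <- generate_fixture()
  report <- run_all_checks(wb)
  st <- ark_minter(withr::local_tempfile())
  ark <- mint_ark(st)$identifier
  cit <- make_citation(ark = ark)
  out <- file.path(withr::local_tempdir(), "pkg")
  pkg <- build_package(wb, cit$metadata, cit, out, report = report)

  root <- file.path(withr::local_tempdir(), "repo")
  receipt <- deposit(pkg, fs_adapter(root))
  expect_identical(receipt$identifier$full, ark$full)
  dest <- file.path(root, ark$naan, ark$name)
  expect_true(dir.exists(dest))
  expect_true(isTRUE(verify_manifest(dest)))
  expect_true(all(file.exists(receipt$stored_paths)))
  # receipt identifier matches the packaged metadata's identifier element
  eml <- from_eml(file.path(dest, "eml.xml"))
  expect_identical(eml$file_level$identifier, receipt$identifier$full)
  # double deposit of the same identifier is refused
  expect_error(deposit(pkg, fs_adapter(root)), "already exists")
})

test_that("a package without an identifier gets one minted at deposit", {
  wb <- generate_fixture()
  cit <- make_citation()
  out <- file.path(withr::local_tempdir(), "pkg")
  pkg <- build_package(wb, cit$metadata, cit, out,
                       report = run_all_checks(wb))
  root <- file.path(withr::local_tempdir(), "repo")
  receipt <- deposit(pkg, fs_adapter(root))
  expect_true(validate_ark(receipt$identifier$full)$valid)
  expect_true(dir.exists(file.path(root, receipt$identifier$naan,
                                   receipt$identifier$name)))
})

test_that("unusable repository roots fail authentication with no partial state", {
  # a path under a regular file can never become a writable directory,
  # regardless of the uid running the tests
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)
  wb <- generate_fixture()
  cit <- make_citation()
  out <- file.path(withr::local_tempdir(), "pkg")
  pkg <- build_package(wb, cit$metadata, cit, out,
                       report = run_all_checks(wb))
  expect_error(deposit(pkg, fs_adapter(file.path(blocker, "repo"))),
               "authentication failed")
})
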