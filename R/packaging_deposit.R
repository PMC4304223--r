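#' Assess whether a dataset is ready for repository deposit
#'
#' Readiness gates on three things: a compatibility check has been *run* (not
#' necessarily passed -- users may knowingly archive imperfect data, so
#' `compatibility_passed` is surfaced for the repository but does not gate),
#' the metadata record is complete, and a citation has been generated. The
#' predicate is pure and monotone: satisfying an additional gate never flips
#' readiness off.
#'
#' @param report a `check_report`, or `NULL` if no check was run.
#' @param md a `metadata_record`.
#' @param citation a `data_citation`, or `NULL`.
#' @return a `readiness_result`: `compatibility_checked`,
#'   `compatibility_passed`, `metadata_complete`, `citation_present`,
#'   `ready`.
#' @export
assess_readiness <- function(report, md, citation) {
  checked <- !is.null(report)
  complete <- is_complete(md)
  cited <- !is.null(citation)
  structure(
    list(compatibility_checked = checked,
         compatibility_passed = checked && report$passed,
         metadata_complete = complete,
         citation_present = cited,
         ready = checked && complete && cited),
    class = "readiness_result")
}

#' @export
print.readiness_result <- function(x, ...) {
  mark <- function(b) if (b) "yes" else "no"
  cat("Deposit readiness:", if (x$ready) "READY" else "not ready", "\n")
  cat("  compatibility check run:   ", mark(x$compatibility_checked), "\n")
  cat("  compatibility check passed:", mark(x$compatibility_passed), "\n")
  cat("  metadata complete:         ", mark(x$metadata_complete), "\n")
  cat("  citation generated:        ", mark(x$citation_present), "\n")
  invisible(x)
}

file_sha256 <- function(path) {
  digest::digest(file = path, algo = "sha256")
}

mime_of <- function(path) {
  switch(tolower(tools::file_ext(path)),
    csv = "text/csv", xml = "application/xml", json = "application/json",
    ris = "application/x-research-info-systems", bib = "application/x-bibtex",
    txt = "text/plain", "application/octet-stream")
}

#' Assemble a deposit package
#'
#' Builds a self-verifying package directory: `data/` with one exported CSV
#' per non-empty sheet, `eml.xml`, the citation in all three formats
#' (`citation.ris`, `citation.bib`, `citation.xml`), a technical-metadata
#' JSON (per-file name, size, SHA-256 checksum and MIME label plus package
#' totals), and a BagIt-style `manifest-sha256.txt` covering every payload
#' file so fixity can be re-verified after any transfer.
#'
#' @param wb a `wb_workbook`.
#' @param md a complete `metadata_record`.
#' @param citation a `data_citation`.
#' @param out_dir directory to create the package in.
#' @param report optional `check_report`; readiness requires one.
#' @return a `deposit_package`: `dir`, `files` (manifest-relative paths),
#'   `tech_metadata`, `identifier`.
#' @export
build_package <- function(wb, md, citation, out_dir, report = NULL) {
  readiness <- assess_readiness(report, md, citation)
  if (!readiness$ready) {
    missing <- c(
      if (!readiness$compatibility_checked) "compatibility check not run",
      if (!readiness$metadata_complete) "metadata incomplete",
      if (!readiness$citation_present) "citation not generated")
    stop("dataset is not ready for deposit: ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  dir.create(file.path(out_dir, "data"), recursive = TRUE, showWarnings = FALSE)
  csvs <- export_csv(wb, file.path(out_dir, "data"))
  to_eml(citation$metadata, file.path(out_dir, "eml.xml"))
  for (fmt in c("ris", "bib", "xml")) {
    export_citation(citation, fmt, file.path(out_dir, paste0("citation.", fmt)))
  }
  payload <- c(file.path("data", basename(csvs)), "eml.xml",
               "citation.ris", "citation.bib", "citation.xml")
  tech <- data.frame(
    name = payload,
    size = vapply(file.path(out_dir, payload), file.size, numeric(1)),
    sha256 = vapply(file.path(out_dir, payload), file_sha256, character(1)),
    format = vapply(payload, mime_of, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  tech_md <- list(files = tech,
                  total_files = nrow(tech), total_bytes = sum(tech$size),
                  compatibility_passed = readiness$compatibility_passed,
                  identifier = citation$metadata$file_level$identifier)
  jsonlite::write_json(tech_md, file.path(out_dir, "techmd.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(paste0(tech$sha256, "  ", tech$name),
             file.path(out_dir, "manifest-sha256.txt"))
  structure(
    list(dir = out_dir, files = payload, tech_metadata = tech_md,
         identifier = citation$identifier),
    class = "deposit_package")
}

#' Verify a package's BagIt-style manifest
#'
#' @param dir package directory containing `manifest-sha256.txt`.
#' @return `TRUE` if every listed file exists and its SHA-256 matches;
#'   otherwise `FALSE` with attribute `"failures"` naming the mismatches.
#' @export
verify_manifest <- function(dir) {
  mf <- file.path(dir, "manifest-sha256.txt")
  if (!file.exists(mf)) {
    return(structure(FALSE, failures = "manifest-sha256.txt missing"))
  }
  lines <- readLines(mf, warn = FALSE)
  failures <- character()
  for (line in lines) {
    m <- regmatches(line, regexec("^([0-9a-f]{64})  (.+)$", line))[[1]]
    if (length(m) != 3) { failures <- c(failures, line); next }
    path <- file.path(dir, m[3])
    if (!file.exists(path) || !identical(file_sha256(path), m[2])) {
      failures <- c(failures, m[3])
    }
  }
  if (length(failures) > 0) structure(FALSE, failures = failures) else TRUE
}

#' Filesystem repository adapter
#'
#' The repository seam: an adapter must provide `authenticate()` (returning
#' an authenticated session or erroring), `mint(session)` (returning an
#' identifier), and `store(session, package, identifier)` (returning stored
#' paths). The bundled filesystem adapter deposits under
#' `<root>/<naan>/<name>/`, re-verifies the manifest after copying, and
#' removes any partial copy on failure. Network repository protocols plug in
#' behind the same contract.
#'
#' @param root target directory playing the repository role.
#' @param minter_state an [ark_minter()] state (or state-file path); defaults
#'   to a `minter` file under `root`.
#' @return an adapter object for [deposit()].
#' @export
fs_adapter <- function(root, minter_state = NULL) {
  structure(list(root = root, minter_state = minter_state),
            class = "fs_adapter")
}

adapter_authenticate <- function(adapter) UseMethod("adapter_authenticate")
adapter_mint <- function(adapter, session) UseMethod("adapter_mint")
adapter_store <- function(adapter, session, pkg, identifier) {
  UseMethod("adapter_store")
}

#' @export
adapter_authenticate.fs_adapter <- function(adapter) {
  dir.create(adapter$root, recursive = TRUE, showWarnings = FALSE)
  ok <- file.access(adapter$root, mode = 2) == 0
  if (!ok) {
    stop("repository authentication failed: '", adapter$root,
         "' is not writable", call. = FALSE)
  }
  list(root = normalizePath(adapter$root))
}

#' @export
adapter_mint.fs_adapter <- function(adapter, session) {
  state <- adapter$minter_state %||% file.path(session$root, "minter")
  if (is.character(state)) {
    state <- if (file.exists(state)) read_minter_state(state) else
      ark_minter(state)
  }
  mint_ark(state)$identifier
}

#' @export
adapter_store.fs_adapter <- function(adapter, session, pkg, identifier) {
  dest <- file.path(session$root, identifier$naan, identifier$name)
  if (dir.exists(dest)) {
    stop("deposit target already exists: ", dest, call. = FALSE)
  }
  dir.create(dest, recursive = TRUE)
  srcs <- list.files(pkg$dir, recursive = TRUE)
  for (rel in srcs) {
    dir.create(file.path(dest, dirname(rel)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(pkg$dir, rel), file.path(dest, rel))
  }
  ok <- verify_manifest(dest)
  if (!isTRUE(ok)) {
    unlink(dest, recursive = TRUE)
    stop("manifest verification failed after transfer (",
         paste(attr(ok, "failures"), collapse = ", "),
         "); partial deposit removed", call. = FALSE)
  }
  file.path(dest, srcs)
}

#' Deposit a package into a repository
#'
#' Authenticates against the adapter, mints an identifier if the package
#' does not already carry one, stores the package, and returns a receipt.
#'
#' @param pkg a `deposit_package` from [build_package()].
#' @param adapter a repository adapter such as [fs_adapter()].
#' @return a `deposit_receipt`: `identifier`, `repository_id`,
#'   `stored_paths`, `deposited_at`.
#' @export
deposit <- function(pkg, adapter) {
  session <- adapter_authenticate(adapter)
  identifier <- pkg$identifier %||% adapter_mint(adapter, session)
  stored <- adapter_store(adapter, session, pkg, identifier)
  structure(
    list(identifier = identifier,
         repository_id = paste0("fs:", session$root),
         stored_paths = stored,
         deposited_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    class = "deposit_receipt")
}

#' @export
print.deposit_receipt <- function(x, ...) {
  cat("Deposit receipt\n")
  cat("  identifier:", x$identifier$full, "\n")
  cat("  repository:", x$repository_id, "\n")
  cat("  files stored:", length(x$stored_paths), "\n")
  cat("  deposited at:", x$deposited_at, "\n")
  invisible(x)
}
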