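#' ARK identifier minting and validation
#'
#' An ARK (Archival Resource Key) has the form `ark:/<naan>/<name>`, where
#' the NAAN is a 5-digit name-assigning-authority number and the name is a
#' shoulder (a short fixed prefix) plus a blade. This package ships a local,
#' stateful test minter under the ARK test NAAN 99999: it needs no network,
#' persists a monotone counter in a plain-text state file between calls, and
#' never reissues an identifier for a given state file. Blades encode the
#' counter in the vowel-free "extended digits" alphabet conventionally used
#' by noid-style minters, so identifiers stay opaque and transcription-safe.
#' The default shoulder `"fk4"` is the conventional test shoulder and is
#' arbitrary. A remote minter can replace this one behind the repository
#' adapter seam.
#'
#' @param path state file location.
#' @param naan 5-digit NAAN string.
#' @param shoulder shoulder string prefixed to every minted name.
#' @return `ark_minter()` returns the state as a list (`path`, `naan`,
#'   `shoulder`, `counter`).
#' @examples
#' st <- ark_minter(tempfile())
#' minted <- mint_ark(st)
#' minted$identifier$full
#' @name ark
NULL

EXTENDED_DIGITS <- strsplit("0123456789bcdfghjkmnpqstvwxz", "")[[1]]

encode_blade <- function(n) {
  base <- length(EXTENDED_DIGITS)
  if (n == 0) return(EXTENDED_DIGITS[1])
  out <- character()
  while (n > 0) {
    out <- c(EXTENDED_DIGITS[(n %% base) + 1], out)
    n <- n %/% base
  }
  paste(out, collapse = "")
}

#' @rdname ark
#' @export
ark_minter <- function(path, naan = "99999", shoulder = "fk4") {
  if (!grepl("^[0-9]{5}$", naan)) {
    stop("NAAN must be exactly 5 digits, got '", naan, "'", call. = FALSE)
  }
  if (file.exists(path)) return(read_minter_state(path))
  state <- list(path = path, naan = naan, shoulder = shoulder, counter = 0L)
  write_minter_state(state)
  state
}

read_minter_state <- function(path) {
  bad <- function(why) {
    stop("corrupt minter state file '", path, "': ", why,
         " -- refusing to mint (identifiers must never be reused); ",
         "remove or repair the file explicitly", call. = FALSE)
  }
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) bad(conditionMessage(e)))
  kv <- regmatches(lines, regexec("^([a-z]+): *(.*)$", lines))
  kv <- kv[vapply(kv, length, integer(1)) == 3]
  fields <- stats::setNames(vapply(kv, `[`, character(1), 3),
                            vapply(kv, `[`, character(1), 2))
  if (!all(c("naan", "shoulder", "counter") %in% names(fields))) {
    bad("missing naan, shoulder or counter field")
  }
  counter <- suppressWarnings(as.integer(fields[["counter"]]))
  if (is.na(counter) || counter < 0) bad("counter is not a non-negative integer")
  if (!grepl("^[0-9]{5}$", fields[["naan"]])) bad("naan is not 5 digits")
  list(path = path, naan = fields[["naan"]],
       shoulder = fields[["shoulder"]], counter = counter)
}

write_minter_state <- function(state) {
  writeLines(c(paste0("naan: ", state$naan),
               paste0("shoulder: ", state$shoulder),
               paste0("counter: ", state$counter)),
             state$path)
  invisible(state)
}

#' Mint the next ARK from a minter state
#'
#' @param state a minter state from [ark_minter()], or a state-file path.
#' @param shoulder optional shoulder overriding the state's.
#' @return a list with `identifier` (an `ark_identifier`: `scheme`, `naan`,
#'   `name`, `full`) and the updated `state` (also persisted to the state
#'   file).
#' @export
mint_ark <- function(state, shoulder = NULL) {
  if (is.character(state)) state <- read_minter_state(state)
  shoulder <- shoulder %||% state$shoulder
  name <- paste0(shoulder, encode_blade(state$counter))
  state$counter <- state$counter + 1L
  write_minter_state(state)
  identifier <- structure(
    list(scheme = "ark", naan = state$naan, name = name,
         full = paste0("ark:/", state$naan, "/", name)),
    class = "ark_identifier")
  list(identifier = identifier, state = state)
}

#' Validate and parse an ARK string
#'
#' Checks the `ark:/NAAN/name` pattern (5-digit NAAN; name restricted to the
#' ARK-safe character set, no whitespace) and parses it into its parts.
#' Hyphens in ARKs are "identity inert": they may be inserted anywhere for
#' readability and are ignored when comparing, which [ark_equal()]
#' implements.
#'
#' @param s a candidate identifier string.
#' @return a list: `valid` (logical) and, when valid, `identifier` (an
#'   `ark_identifier`).
#' @export
validate_ark <- function(s) {
  m <- regmatches(s, regexec("^ark:/([0-9]{5})/([A-Za-z0-9=~*+@_$.-]+)$", s))[[1]]
  if (length(m) != 3) return(list(valid = FALSE))
  list(valid = TRUE, identifier = structure(
    list(scheme = "ark", naan = m[2], name = m[3], full = s),
    class = "ark_identifier"))
}

#' @rdname validate_ark
#' @param a,b ARK strings or `ark_identifier`s.
#' @export
ark_equal <- function(a, b) {
  norm <- function(x) {
    if (inherits(x, "ark_identifier")) x <- x$full
    gsub("-", "", x, fixed = TRUE)
  }
  identical(norm(a), norm(b))
}

#' @export
print.ark_identifier <- function(x, ...) {
  cat(x$full, "\n")
  invisible(x)
}
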