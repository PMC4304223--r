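Package: curatr
Title: Spreadsheet Curation for Repository Deposit
Version: 0.1.0
Authors@R:
    person("Data", "Curator", email = "curator@example.org", role = c("aut", "cre"))
Description: Lints tabular spreadsheet workbooks against eleven published
    data-management best-practice rules, exports archive-ready RFC 4180 CSV,
    builds and serializes a 47-element Ecological Metadata Language (EML)
    metadata subset, generates data citations (RIS, BibTeX, DataCite-style
    XML), mints ARK persistent identifiers with a local test minter, and
    assesses and packages datasets for repository deposit through a pluggable
    adapter with a filesystem backend. Includes a deterministic fixture
    generator so every rule is testable without external data, and a
    command-line interface covering the full check/describe/cite/deposit
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    optparse,
    readr,
    xml2,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
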