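# curatr

Spreadsheets are where most tabular research data is born, and where much of
it dies: embedded charts, cell comments, color coding, merged cells and
multi-table tabs all evaporate or corrupt when a workbook is flattened to
CSV for a data repository. `curatr` is an R toolkit for researchers and data
managers who need to get spreadsheet data from "works on my laptop" to
"archived, documented and citable":

* **Best-practices linting** — a closed catalogue of 11 rules covering the
  spreadsheet features that break CSV export or machine readability
  (embedded objects, comments, commas inside cells, special characters,
  color coding, mixed-type columns, non-contiguous tables, merged cells,
  interior blank cells, header problems, multiple sheets). Every finding is
  located to the cell and accompanied by a "why it is a problem" paragraph
  and a suggested remedy.
* **Archive-ready export** — RFC 4180 CSV with one file per non-empty
  sheet, shortest-round-trip numbers and ISO 8601 dates, plus bulk
  remediation transforms (comments to a `Comments` column, strip
  formatting/objects, unmerge-and-fill).
* **Metadata** — a 47-element subset of the Ecological Metadata Language
  (EML), 7 elements required, with completeness validation, lossless EML
  XML serialization, and embedding as a `Metadata` tab in the workbook
  itself.
* **Citation and identifiers** — DataCite-style data citations exported as
  `.ris`, `.bib` or DataCite-flavoured XML, and ARK persistent identifiers
  from a local, stateful test minter (NAAN 99999) with hyphen-insensitive
  validation.
* **Deposit packaging** — readiness assessment, a BagIt-style
  SHA-256-manifested package, and a pluggable repository adapter with a
  filesystem backend that re-verifies fixity after transfer.

A deterministic fixture generator (`generate_fixture()`) can inject each of
the 11 defects at recorded locations, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(curatr)

wb <- generate_fixture(c("embedded_comments", "merged_cells"), seed = 42)
report <- run_all_checks(wb)
cat(render_report(report, "text"))
```

```
Best practices check report
Source: <in-memory>
Checked at: 2026-09-09T17:12:12Z
Result: issues found (2 issues)

[warning] Embedded comments. (sheet: data)
  Locations: B3, D5
  Why: Comments will not be visible when data are exported as a .csv file. Also, these elements are visible only if the file is opened with Microsoft Excel.
  Suggested remedy: Create a new column titled “Comments” and add your text there.

[warning] Merged cells. (sheet: data)
  Locations: F6:G7
  Why: Merged cells will not be maintained when data are exported as a .csv file. Information may be lost when cells are un-merged upon export.
  Suggested remedy: Un-merge cells and annotate appropriately so information is not lost.
```

The two issues are exactly the injected defects: comments on cells `B3` and
`D5`, and the merged range `F6:G7`. Both rules are auto-fixable, so
`remediate_all(wb)` silences them; the rest of the pipeline then runs:

```r
wb <- remediate_all(wb)
report <- run_all_checks(wb)            # passed: TRUE

md <- prepopulate(wb)                   # date, creator, title from doc properties
region <- detect_regions(wb$sheets[[1]])[[1]]
md <- new_metadata(md$file_level, attributes_from_header(region, wb$sheets[[1]]))
md <- set_elements(md, abstract = "Eight survey sites.", keywords = "survey",
                   creator_email = "ana@example.org")
is_complete(md)                         # TRUE: all 7 required elements present

ark <- mint_ark(ark_minter("minter"))$identifier   # ark:/99999/fk40
cit <- build_citation(md, 2013, identifier = ark)
cit$formatted
# "Mendez, Ana (2013): field_samples. Example Data Repository. ark:/99999/fk40."

pkg <- build_package(wb, cit$metadata, cit, "pkg_out", report = report)
receipt <- deposit(pkg, fs_adapter("repo"))
verify_manifest(file.path("repo", "99999", "fk40"))   # TRUE
```

## Command line

The same pipeline is available as a CLI (see `exec/curatr` and
`?run_cli`): `check` (with `--strict` and `--report json`), `export`,
`metadata init|validate|embed`, `cite`, `mint`, `package`, `deposit`
(against `--repo fs:PATH`) and `fixture`.

## Limitations

Only `.xlsx` and `.csv` inputs are supported (no legacy `.xls`, no other
office formats); formulas are carried as text plus cached value but never
evaluated; embedded charts/pictures/pivot tables are modeled as
presence-plus-anchor stubs; theme-indexed colors resolve to "default". See
the methods vignette (`vignettes/curation-pipeline.Rmd`) for the design
rationale behind the heuristics.
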