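---
title: "From spreadsheet to repository: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spreadsheet to repository: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curatr)
```

`curatr` turns a spreadsheet workbook into a deposit-ready data package:
lint, export, describe, cite, identify, package, deposit. This vignette
documents the model behind each stage, the parameters that matter, and the
places where the design was genuinely open and a choice had to be made.
Nothing here states an empirical result that the test suite does not itself
compute.

## The workbook model

Everything operates on a neutral in-memory model (`wb_workbook`): an ordered
list of sheets, each a sparse set of cells with a value, a *kind* (`empty`,
`number`, `text`, `date`, `boolean`, `error`), and optional annotations
(formula text plus cached value, comment, fill color, font color), plus
merged ranges and embedded-object anchors. Three modeling decisions shape
the checks:

* **Colors are normalized hex RGB; "no explicit formatting" is `NA`, never
  a hex value.** The color-coding rule needs a crisp predicate for "this
  cell was deliberately shaded"; encoding the default as white would
  conflate formatted and unformatted cells. Theme-indexed colors that
  cannot be resolved are treated as default, a conservative choice that can
  miss theme-based shading but never fabricates a finding.
* **Formula cells carry both the formula text and the cached value, and
  checks operate on the cached value.** The linter judges what a CSV export
  would contain; evaluating formulas is out of scope.
* **Charts, pictures and pivot tables are presence plus anchor only.** The
  embedded-objects rule needs existence and location, nothing else. The
  `.xlsx` writer emits minimal valid stub parts for them; they are not
  guaranteed to render in a spreadsheet application.

I/O supports Office Open XML `.xlsx` (read and write, including comments,
fills, merges and document properties) and RFC 4180 CSV with UTF-8/BOM
tolerance. Cells read from CSV are type-sniffed by `value_kind_of()`: text
is a number iff it parses as a decimal or scientific-notation literal, a
date iff it is a valid `YYYY-MM-DD` calendar date, otherwise text. Date
sniffing is deliberately strict (ISO 8601 only): regional formats like
`01/02/2011` are ambiguous and stay text. This also makes CSV export
followed by re-reading lossless for numbers, dates and text, which the
tests assert; booleans serialize as `TRUE`/`FALSE` and return as text,
documented as the one lossy kind. Dates are written to `.xlsx` as
ISO-typed cells (`t="d"`); date-as-serial-number cells written by other
software are read as numbers, a known limitation.

## Finding tables and headers

Several rules are scoped to *table regions*. The source best-practice texts
frame empty rows and columns as table separators but do not define a
detection algorithm, so the one here is an explicit reconstruction:
recursively split the used range at rows, then columns, that are entirely
empty within the current block, trimming each block to the bounding box of
its non-empty cells. This is deterministic, produces rectangles, and yields
a partition: every valued cell lies in exactly one region. A consequence
worth noting: an isolated valued cell is its own one-cell region, so "cells
outside regions" can only be annotation-bearing empty cells (a stray fill
or comment), and those are exactly what region scoping exempts.

Header detection is likewise a reconstruction. The top row of a region is a
header iff all its cells are text, none is empty across the region's width,
and its values are unique (case-sensitive exact match — the guidance asks
for "unique parameter names" without defining collation). Additional
consecutive all-text, fully populated rows are absorbed into a multi-row
header only while at least half of the region's columns still hold a
non-text value below the rows counted so far. The half-columns guard exists
for text-only tables (e.g. site × habitat lookups): without it, a
categorical table would swallow itself row by row into an ever-deeper
"header". A text first row over all-text columns is therefore *not* a
header failure; headerness rests on the uniqueness and no-empty-cell
predicates alone.

## The 11 rules

The catalogue is a closed, ordered set of 11 rules, each carrying verbatim
"why" and "suggested remedy" texts shown to users. Scoping follows the
remedies' own framing: rules about cell contents (commas, special
characters, color coding, mixed types, blank cells) run inside detected
regions; rules about workbook furniture (embedded objects, comments, merged
cells, multiple sheets) are global. Issues aggregate locations per
(rule, sheet) so large files produce readable reports.

Three under-specified points are resolved as package decisions:

* **The allowed character set for the special-characters rule** is ASCII
  letters, digits, space and `. _ - ( ) /`. The guidance says only "use
  alpha-numeric characters only"; parentheses, slash, period, underscore
  and hyphen are admitted as archival-safe because they are ubiquitous in
  unit strings and site codes and survive every CSV consumer we know of.
  Commas are excluded here because the commas rule owns them — one
  character never fires two rules.
* **Mixed types** partitions the non-empty cells of each region column
  below the header by kind; two or more of {number, text, date, boolean}
  flags the column as a rectangle. Excluding the header is what lets a text
  label sit over a numeric column without a false positive; for headerless
  regions all rows participate.
* **Duplicate header labels** are folded into the header rule (as a
  "duplicate" detail) rather than becoming a twelfth rule, preserving the
  closed 11-rule set.

Severity is `"warning"` for all rules except multiple sheets, which is
`"info"`: the export stage handles it automatically by splitting, so it is
advisory rather than actionable.

## Export and remediation

CSV export writes one file per non-empty sheet (`<stem>_<sheet>.csv`,
sanitized, collision-suffixed), LF line endings and UTF-8 without BOM by
default (a `crlf` option exists for legacy consumers). Numbers use the
shortest decimal rendering that survives a parse round-trip; merged ranges
contribute their anchor value at the top-left cell and empties elsewhere,
which is what spreadsheet applications themselves do on export.

The remediation transforms implement only the remedies that need no human
judgment: relocating comments into a `Comments` column (joined `"; "` in
column order within a row), stripping formatting and objects, and
unmerge-with-fill, which replicates the anchor value into the whole former
range — the information-preserving reading of "un-merge and annotate
appropriately". Commas, special characters, mixed types and blank cells are
reported but never auto-fixed; their remedies require understanding what
the data means. All transforms are pure (input workbooks are never mutated)
and idempotent, and applying them all silences exactly the four fixable
rules, which the tests assert.

## The metadata schema

The schema is a 47-element subset of EML with 7 required elements (today's
date, dataset title, abstract, keywords, creator first name, last name and
email). The published element table enumerates 42 file-level elements
(7 basic + 20 personnel + 15 dataset); the count of 47 is reached by the 5
attribute-level elements describing each data-table column: parameter name,
description, units, measurement type and missing-value code. This split is
an interpretation — the table's typesetting does not spell it out — but it
is the unique reading consistent with both printed counts, and it is pinned
by tests.

Completeness is exactly the 7-required predicate: filling any six leaves
the record incomplete. Validation additionally enforces the invariants that
have crisp definitions: ISO dates, `@` in email addresses, bounding
coordinates within range with south ≤ north. Units are free text; no
controlled vocabulary is imposed.

EML serialization targets the EML 2.1.1 element vocabulary
(`creator/individualName`, `coverage/boundingCoordinates`,
`dataTable/attributeList/attribute/...`) but does not validate against the
XSD: the contract is well-formedness plus a lossless field-by-field
round-trip through `from_eml()`, which is cheaper, dependency-free, and
what downstream indexing actually needs. The same record also embeds as a
`Metadata` tab (element-name/value rows in schema order, attributes as a
small table), and the two serializations are mutually consistent:
embed → extract → `to_eml()` equals `to_eml()` directly.

## Citations and identifiers

Citations follow the DataCite style — `Creator(s) (Year): Title.
Publisher. Identifier.` — because no style was prescribed; creators render
`"Last, First"` joined by `"; "`. The formatted string is written back into
the record's formatted-citation element so the citation is part of the
metadata, and exports to RIS (`TY  - DATA`), a single BibTeX `@misc` entry,
and a DataCite-style XML resource, all carrying identical content.

Identifiers are ARKs minted locally under the test NAAN 99999 with the
conventional test shoulder `fk4` (both arbitrary and configurable). The
minter persists `naan`/`shoulder`/`counter` in a plain-text state file;
blades encode the counter in the vowel-free noid alphabet. A corrupt state
file is a hard error — silently restarting the counter could reissue
identifiers, the one unforgivable minter failure. Hyphens are identity-inert
in comparisons, per the ARK scheme's transcription rule. Live
resolution/minting services are out of scope; the repository adapter is the
seam where a remote minter would plug in.

## Readiness and deposit

Deposit readiness gates on three predicates: a compatibility check **has
been run**, metadata is complete, and a citation exists. Whether the check
*passed* is surfaced (`compatibility_passed`) but does not gate — the
stated requirement is that the check be completed, and users may knowingly
archive imperfect data; blocking on a zero-issue report would make the
linter a gatekeeper rather than an advisor. This gating reading is a
documented decision, not an attested behavior of any prior system.

Packages are BagIt-flavoured: `data/` CSVs, `eml.xml`, three citation
files, a `techmd.json` (per-file size, SHA-256, MIME label, totals) and a
`manifest-sha256.txt` covering every payload file. The filesystem adapter
authenticates by verifying the root is writable, stores under
`<root>/<naan>/<name>/`, re-verifies the manifest after the copy, and
removes the partial copy on mismatch. Flipping a single payload byte at the
destination makes verification fail, which the tests do literally.

## The fixture generator, and what green tests mean

`generate_fixture()` states a small but realistic world: one
field-survey-style table (unique text header; text site codes; ISO dates;
two numeric measurement columns; eight data rows) with seeded filler values
— seeds drive values only, never structure. Each of the 11 defects can be
injected at recorded locations, and injections are constructed to be
pairwise independent. Two constructions carry that guarantee: the header
defect adds a second all-text sub-header row (replacing header text with
numbers would make the text and date columns mixed-type), and the merged
range sits over empty cells away from any region (a merge inside the table
would create interior blanks; a valued merge outside would create a second
region). The multiple-sheets defect adds a second, itself-pristine sheet.

The generator emulates the *structural* failure modes of real spreadsheets,
not their statistical ones. It does not produce ragged encodings, locale
number formats, formula-driven values, fifty-sheet workbooks, or the
ambiguous half-header layouts humans actually type. A green
injection/detection suite therefore establishes that each rule fires
exactly where its defect is and nowhere else *in this stated world*; it
does not establish recall on arbitrary real-world workbooks, where the
region and header heuristics are reconstructions with known failure modes
(transposed tables, header columns, pivot-table output).

## Numerical and degenerate-input choices

* Number serialization searches 1–17 significant digits for the shortest
  round-trip form; integers below 10^15 print without exponent.
* Empty sheets yield no regions; an empty workbook refuses CSV export with
  an explicit error rather than writing nothing.
* Header uniqueness and all comparisons are byte-exact and case-sensitive.
* Cell addressing is 1-based with A1 rendering, matching what users see in
  their spreadsheet application when they cross-check a report location.
* The report timestamp is the only non-deterministic report field; JSON
  reports are byte-stable across runs once it is removed, which the CLI
  tests assert.
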