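---
title: "Indexing SDS composition tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing SDS composition tables: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdsindex)
```

## The problem and the pipeline's shape

A Safety Data Sheet is a semi-structured document: its sixteen sections
follow a mandated order, but layout varies freely across manufacturers.
The composition block (Section 3, or Section 2 on older sheets) may be a
bordered table, a borderless aligned grid, free-running text, row- or
column-oriented, split across a page boundary, or absent altogether for
non-hazardous products. A single end-to-end extractor must cope with all
of that at once; a pipeline of narrow stages, each of which only shrinks
the search space for the next, is much easier to make precise. That is the
design here: each stage either narrows the region of interest (pages, then
rectangles, then grid cells) or fails the document with a stage-named
reason, so batch runs degrade record by record instead of crashing.

The pipeline is tuned to favour precision over recall: every stage
prefers returning nothing (and triggering a fallback or a FAILED status)
over guessing. A record that reaches the output has survived a header
match, an evidence check, a geometric alignment test, and a regex-backed
column assignment.

## Stage-by-stage model

**Text extraction.** Three extraction backends sit behind one interface;
for each page the first backend in preference order that produces
non-whitespace text wins, and the winning backend is recorded. Falling
back per page (rather than per document) loses nothing and recovers mixed
documents where a single malformed page defeats the primary backend. Only
the primary (layout) backend supplies per-character geometry; documents
read through the weaker backends can still pass the no-data filter and
page selection, which need text only. Character coordinates come from the
PDF text layer directly — for text-based PDFs the text layer is lossless,
so no rasterisation or OCR is involved anywhere in the default path.
Preprocessing applies, in order: newline removal, trimming, lower-casing,
stopword removal. The stopword list is pinned in the package (articles,
conjunctions, prepositions) so outputs are reproducible; it deliberately
excludes negation-ish tokens ("no", "not", "none") that carry meaning on
an SDS. Section headers are matched on the raw, pre-stopword text, since
stopword removal could damage phrases like "information on ingredients".
No de-hyphenation or ligature repair is attempted.

**No-data filter.** Real corpora contain a material fraction of sheets
with no composition information at all (roughly 6–8% of documents in the
population this emulates). The filter concatenates the preprocessed text
of all pages, splits it into non-overlapping chunks of `max_chunk_len`
tokens (default 256), classifies each chunk, and declares the document
`NO_DATA` exactly when no chunk is predicted to contain ingredient
information. The chunk classifier is an interface: the default is a
deterministic rule (a chunk has data iff it matches the CAS regex, an
ingredient-label pattern, or contains a gazetteer name); a trainable
bag-of-tokens ridge-logistic classifier (glmnet) ships alongside to
exercise the train/predict path. For gold labelling of chunks, a chunk is
negative (has data) if it contains any gold name token, gold CAS string,
or gold weight string after the same preprocessing — "any of the three
fields" rather than a single designated field, which is the permissive
reading and the one that makes the oracle-classifier property (gold chunk
labels reproduce the gold document status) hold by construction.

**Page selection.** Begin/end header patterns ship in a versioned pattern
file (`inst/extdata/header_patterns.tsv`, one `id TAB kind TAB regex` per
line). Patterns couple the section number to the section title
("section 3 … composition", "section 3 … hazards identification") so that
the legacy numbering (composition in Section 2, hazards in Section 3)
disambiguates from the modern one without a document-level format switch.
The four rules run in order: both headers on a page with evidence between;
begin-only with evidence after; end-only with evidence before (the last
two are what recover tables split across a page break); and finally the
Section-1 fallback — if nothing was selected and Section 1 contains a CAS
number, page 1 is the answer and the product itself is the single
ingredient. Section 1 is delimited as document start to the first
Section-2/3 header; failing that, the first page. For sections spanning
three or more pages, interior marker-free pages are included when they
carry evidence; this situation does not arise in the synthetic corpus but
the rule is cheap and strictly widens recall. Multiple begin headers on
one page use the first, with a warning.

**Region detection.** The default table detector is a layout heuristic
over word geometry: group words into lines; call a line *strong* if it has
at least two column groups (separated by horizontal gaps of at least
`col_gap_pt`, default 12 pt); chain consecutive strong lines that share at
least two x-aligned group starts (tolerance `x_tol`, default 6 pt) and sit
within 2.8 line-heights of each other; require the run to contain a CAS
token (numeric or sentinel) or a weight token; report the run's bounding
box. Single-group lines interior to a run whose start aligns with a run
column are absorbed (wrapped cell continuations); a *trailing*
single-group line is absorbed only when it fits entirely inside one column
band, so that a following section header — which crosses column
boundaries — is never swallowed. Detection is evaluated by IoU with the
half-open-box convention used everywhere in the package (points, top-left
origin, y downward). When no table is found on a selected page, the
fallback region spans from the begin header's character to the end
header's character at full page width, mirroring how the pages were
selected in the first place. The detector is an interface: a learned
detector can be plugged in, in which case page rasterisation becomes that
detector's concern — the default path never builds images.

**Table extraction.** Within a region, words cluster into rows by
vertical proximity (2 pt) and into columns by *global* gutters: maximal
x-intervals crossed by no word, wider than
`max(2 × median intra-word gap, col_gap_pt)`. Global gutters force one
column assignment for the whole region, which is what lets the row
structure carry the name–CAS–weight association. A region with no gutters
(free-running text) degenerates to a single-column grid — the intended
behaviour, see association below. Gridding conserves characters: the
multiset of non-whitespace characters in the cells equals that of the
region. Wrongly split rows are repaired after a provisional column-role
pass: a row whose CAS and weight cells are empty but whose name cell is
filled is folded into the nearest preceding anchored row; a first row made
of label vocabulary with no CAS/weight anywhere is a header row and never
merges. The repair is idempotent and skipped entirely for single-column
grids, where "name column" is not distinct.

**Ingredient extraction.** Grids serialise row-wise with `[cs]`/`[rs]`
separators and `NA` for empty cells — the layout-preserving convention the
recognizer interface is specified against; the serialisation is exactly
invertible. The default recognizer is a longest-match gazetteer over the
packaged chemical vocabulary; any token-labelling function with the same
signature can replace it. Because separator tokens are always OUTSIDE, a
recognised run can never cross a cell boundary, and each assembled name
carries its source cell directly. Orientation is decided per grid: two or
more numeric CAS matches inside a single row, or two or more
label-vocabulary cells down the first column, flag a column-oriented grid,
which is transposed before column identification. The label-column cue is
what keeps split column-oriented fragments (label column repeated on the
continuation page, possibly with a single value column) on the correct
path. The CAS column is the column with the most CAS-or-sentinel matches,
the weight column the most weight-grammar matches excluding the CAS
column; ties go leftmost with a warning. Checksum failures annotate a CAS
(`checksum_valid = FALSE`) but never reject it. Single-column grids use
per-cell association: first CAS match in the cell, weight searched (with a
mandatory percent anchor) in the cell text left after removing the name
and the CAS. Duplicate extracted rows across overlapping regions collapse
to one.

**Weight grammar.** The operator set is `-`, `>`, `<`, `=`, `NaN`. The
pinned dialect: ranges via `-`, en/em dash, or "to", comparators tolerated
on either end (">=1 - <5" reads as the range 1–5); `<`/`≤`/"up to"/"x max"
give an upper bound; `>`/`≥`/"x min" a lower bound; a bare number is
exact (`=`); decimal commas, `%`/`wt%`/`w/w` decorations and Unicode dash
variants are normalised; anything else — including cells that contain a
CAS pattern, which protects "7732-18-5" from being read as a range — maps
to the all-`NaN` spec. The parser is total: every string yields a spec
satisfying the operator invariants.

**Evaluation.** Tier 1 scores each entity kind as a multiset
intersection between predicted and gold values (absent values count as a
distinguished `NA` token); Tier 2 matches whole records under exact
five-field equality — with equality matching, maximum bipartite matching
reduces to multiset intersection, and the test suite checks this against
an exhaustive matcher; Tier 3 scores the document as one unit, correct
only when the record multiset and the status both match. Aggregation is
micro (counts summed, then precision/recall) — chosen and documented
because macro-averaging over documents is ill-defined for the many
documents with one or two records. The combined all-documents metric
folds in gold no-data documents: a correct `NO_DATA` call is one true
positive unit, a spurious record set is a false positive plus a false
negative. Matching is exact equality after normalisation (lower-case,
whitespace-collapsed names; canonical number rendering); no fuzzy name
matching is applied anywhere.

## What the synthetic generator emulates — and what it does not

The generator renders genuine text-based PDFs (PDF 1.4, uncompressed
streams, Courier) of sixteen-section sheets. Courier is metrically fixed,
so the renderer knows every character box exactly, and gold regions are
recorded from the renderer's own geometry rather than annotated after the
fact. Variants cover: bordered/borderless tables, row and column
orientation, tables split across a page boundary (with the header row or
label column repeated on the continuation, as real continued tables do),
free-text composition sections, no-data documents, single-ingredient
products whose only CAS sits in Section 1, and the legacy Section-2
numbering. The noise profile adds wrapped multi-line names, Unicode en/em
dashes in ranges, "Trade Secret" sentinel CAS values, tightened column
gaps, and alternative header phrasings. Default corpus mix: 80% normal
documents cycling through all style × orientation × split combinations,
10% no-data, 10% single-ingredient — the no-data share sits at the upper
edge of the 6–8% prevalence the emulated population reports, rounded up to
keep ten documents of each minority class in a 100-document corpus.
Ingredient counts are drawn uniformly from 2–5; weight operators cycle so
all five kinds appear in any moderate corpus; the name vocabulary mixes
real common chemicals (real registry segments) with combinatorial
salt-style names whose synthetic registry numbers live in a deliberately
high range — check digits are always computed, so every CAS is
checksum-valid either way. A tenth of the vocabulary is held out of the
default gazetteer to measure recognizer-miss behaviour (held-out names are
simply never recognised, costing recall, never precision).

What passing the round-trip tests does **not** show: robustness to real
scanner noise or OCR errors (scanned sheets are out of scope; a page with
no text layer yields empty text and a warning), to multi-column page
layouts, rotated pages, non-English sheets, proportional-font geometry, or
to manufacturer templates with decorative elements between table rows. The
generator's layouts are clean by construction; the noise profile stresses
the stages' logic, not their tolerance to typographic chaos.

## Numerical choices and degenerate inputs

- Coordinates are points, origin top-left, y downward, boxes half-open;
  IoU of a degenerate (zero-area) box is an error, not zero.
- Column-gap threshold 12 pt (two Courier spaces at 10 pt) and alignment
  tolerance 6 pt (one space), both configurable; the gutter threshold
  adapts upward to twice the median intra-word gap.
- Row clustering tolerance 2 pt; line-gap break at 2.8 line-heights.
- Chunk size 256 tokens; chunks never overlap.
- Ties in column identification go leftmost, with a warning; multiple
  begin headers on a page use the first, with a warning.
- Empty documents chunk to an empty list, which aggregates (vacuously) to
  `NO_DATA`; an empty region is an extraction error that fails the
  document with a stage-named reason; a classifier failure on any chunk
  propagates as an error and is never silently read as `NO_DATA`.
- All randomness (sampling, corpus mixing) funnels through R's RNG from a
  single corpus seed; per-document seeds derive arithmetically from it,
  and identical seeds reproduce PDFs byte for byte.

The test suite sizes are: 200 documents for the clean round-trip corpus
(where the pipeline must reproduce gold exactly — document-level precision
and recall 1.0), 100 documents for the noise-profile corpus (precision is
asserted ≥ 0.9; measured recall is reported alongside), 10,000 enumerated
CAS strings for the checksum cross-check, and 1,000 randomised small
prediction/gold pairs for the scorer cross-check.

## Known limitations

- A wrapped name whose continuation line trails the *final* table row is
  kept only when the fragment ends the page; a continuation immediately
  followed by the next section header at normal line spacing is cut, and
  the row's name truncates. Cell contents spanning multiple lines and
  columns sitting very close together are the classic failure modes of
  text-geometry table extraction, and this package shares them.
- Merged (spanning) cells are not recovered.
- Orientation detection needs either two CAS values in a row or a visible
  label column; a one-ingredient column-oriented fragment without labels
  is mis-read as row-oriented.
- The Section-1 fallback trusts the product-identifier label line; a
  missing label falls back to the first Section-1 line with a warning.
- Sentinel vocabulary ("trade secret", "proprietary", "mixture", …) is
  matched on the whole trimmed cell; a sentinel embedded in a longer
  phrase is not recognised.
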