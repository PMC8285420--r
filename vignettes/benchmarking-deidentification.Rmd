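---
title: "Benchmarking DICOM de-identification with synthetic PHI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking DICOM de-identification with synthetic PHI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deidbench)
```

## The problem

Medical images shared for research must have protected health information
(PHI) removed from their DICOM headers, from vendor private attributes, and
from text burned into the pixels themselves. Evaluating a de-identification
algorithm needs ground truth: a dataset where *every* piece of PHI is known,
together with a machine-readable statement of what a correct de-identifier
must do to each of them. Real clinical data cannot provide that ground truth;
a dataset with *synthetic* PHI inserted at known locations can.

`deidbench` manufactures such benchmarks end to end:

1. a **phantom factory** expands a composition manifest (patients, studies,
   series and image counts per modality, with body-part and manufacturer
   assignments) into a clean, PHI-free synthetic DICOM collection;
2. a **PHI forge** generates seeded synthetic identities and attribute
   payloads, including mixed values where PHI sits next to clinically useful
   text;
3. an **injector** applies declarative re-identification operations
   (`set_tag`, `delete_tag`, `shift_date`, `substitute`, `string_replace`,
   `annotate_img`) and logs complete provenance;
4. the provenance is distilled into an **answer key** (actions
   `tag_retained`, `text_notnull`, `text_retained`, `text_removed`,
   `date_shifted`, `uid_changed`, `pixels_hidden`) plus patient-ID and UID
   **crosswalks**;
5. an **evaluator** scores any candidate de-identified dataset against the
   key and scans it for residual PHI leakage.

A reference **oracle de-identifier** applies exactly what the key demands and
must score a perfect report; an **identity copy** must fail every removal,
shift and remap check. Together they bound the score range and validate the
evaluator itself.

## The DICOM layer

The package carries its own minimal DICOM data model: Part-10 files
(128-byte preamble, `DICM` magic), Explicit VR Little Endian, uncompressed,
single frame. This transfer syntax was fixed deliberately — it is the maximally
interoperable choice, and benchmark consumers can convert as needed. The
decoded VR subset covers text (PN, LO, SH, ST, LT, DA, TM, UI, CS, IS, DS),
16/32-bit unsigned binary, and pixel data; any other VR is carried as opaque
bytes and re-serialized byte-identically, so foreign elements survive a
read/write cycle untouched. Sequences are passed through opaquely only; the
injection and evaluation logic needs nothing beyond text, dates, UIDs and
pixels. The character repertoire is ASCII throughout (one catalogued private
attribute historically carried Kanji department names; the toolkit represents
it with an ASCII token instead, since non-ASCII charsets are out of scope).

Private attributes are addressed in creator notation, e.g.
`(0009,"GEMS_PETD_01",37)`: the writer auto-reserves a creator block
`(gggg,00xx)` and renders the element at `xx*256 + 0x37`, and the reader
resolves queries through the reservation elements, never across creators.

## Attribute-type profiles

Each modality's required attributes ship as a CSV transcribing the standard's
requirement levels: Type 1 (required, non-empty), Type 2 (required, may be
empty), conditionals (1C/2C) and optionals. A modality-specific row overrides
the row that applies to all modalities. The table is the published
research-critical subset plus the minimum structural attributes needed to
form readable files (Rows, Columns, Pixel Data, the UID triple, Patient ID,
the image-pixel module). Conditional attributes are never generated and never
injected — the benchmark takes no position on whether their conditions hold.
One transcription choice: Overlay Data `(6000,3000)` is listed as Type 1 for
DX in the source table, which conflicts with overlays being optional in
practice; it is excluded from the shipped profiles rather than guessed at.

`validate_profile_compliance()` checks every generated (and every injected)
instance: zero missing Type 1, zero absent Type 2.

## The phantom factory

The published benchmark selected real archive images; this toolkit
substitutes synthetic phantoms so it is fully self-contained. Pixel realism
is explicitly not a goal — header realism is. Phantom pixels are a smooth
diagonal gradient over [0, 60000] plus seeded Gaussian noise (sd 200,
16-bit), clamped at 64000 so burned-in text (written at 65535) is always
separable from the background. The default matrix is 128x128, which keeps a
full 1,693-image build at desk scale; it is configurable down to 32x32.

Composition counts are honoured *exactly* by a deterministic
largest-remainder allocation: studies round-robin over patients, series over
studies, images over series, with earlier slots taking the remainders. The
bundled fixture manifest reproduces the published collection: 1,693 images —
268 CT, 150 MR, 1,203 PT, 10 DX, 4 CR, 58 MG — across 21 patients, 22
studies and 26 series. Two transcription notes: the per-modality patient
counts sum to 22 while the collection total is 21, so the manifest carries an
explicit patient total and the factory assigns patient slots from a global
pool, wrapping modulo the pool (the final mammography patient reuses the
first CT patient — one patient imaged under two modalities). And the
manifest's labels are copied verbatim without clinical validation:
`VICTRE` appears as a manufacturer label although it is a synthetic-image
collection, and `[BLANK]` is a literal label producing an empty Body Part
Examined value.

Clean instances carry neutral placeholders (`PHANTOM^001`, placeholder
2020-era study dates, birth date `19000101`) so a leakage scan of the clean
dataset against any identity corpus reports zero hits.

## The PHI forge

Identities are a pure function of `(seed, patient index)`: names drawn from
fixed ASCII lists, a 10-digit patient ID whose low six digits come from a
seed-keyed injective permutation of the index (IDs cannot collide within a
cohort), calendar-valid dates with the birth date 18–90 years before the
first study (a plausibility choice; the source material states no range),
accession numbers shaped `YYYYMMDD` + letter + 6 digits, US-style addresses
and phone numbers, per-study physician pairs, and a pool of per-record
auxiliary tokens (serial numbers, department codes, coil IDs...) so that every
injection template owns a distinct string. `make_phi_corpus()` additionally
screens the whole cohort and re-draws a record (with a salted sub-seed) in
the rare event two records share any identity string — this is what makes
"every PHI span maps to exactly one answer-key entry" an exact property
rather than a probabilistic one.

Payload templates assemble attribute values from PHI references and retained
clinical text (e.g. a study description `"Billy Rogers XR CHEST AP
PORTABLE"`: PHI span `"Billy Rogers"`, retained span `"XR CHEST AP
PORTABLE"`). Rendering verifies every span is locatable in the value with no
overlap between PHI and retained positions, longest spans first. The removal
granularity is the full generated fragment (a whole name, a whole accession
number), not individual tokens. The original work generated fakes with a
dedicated Python package; here the behaviour is specified instead — seeded,
locale-stable, shaped fields — so any generator satisfying the invariants is
conformant.

## The injector and its provenance

Directives name a scope (`Collection`, `Patient`, `Study`, `Series`,
`Instance`), a selector, an operation and parameters; plans are JSON-lines
files. Two glosses were resolved as follows: `set_tag` creates-or-overwrites,
while `substitute` only overwrites existing non-empty values and records
skipped instances. Deleting a Type 1 attribute is refused outright — it would
break file validity. `Collection` scope means all patients.

Pixel burn-in uses a built-in 5x7 bitmap font, integrally scalable, with
glyph-only burning: only glyph pixels are set (to the maximum pixel value),
non-glyph pixels inside the rectangle stay untouched, so redaction tests can
distinguish "text present" from "region masked". Coordinates are 0-based
(row, col) with half-open rectangles. Multi-line text stacks with a fixed
one-row leading. The default plan burns `"ID\n<patient id>"` into the first
image of each patient, which requires a pixel matrix of at least 64x64; how
many burn-ins a benchmark carries and where is plan-driven and configurable.

The default plan injects, per patient: name, birth date and patient ID at
Patient scope (ID last — it renames the scope selector); per study: accession
number, referring and performing physicians, and a `shift_date` moving the
placeholder study date onto the identity's synthetic exam date; at the first
study/series: the full unusual-attribute catalogue — roughly twenty standard
attributes (comments, histories, descriptions, device serials, scheduled
dates...) and ten manufacturer private attributes — plus one `substitute`
(mixed study description), one `string_replace` (series description) and the
burn-in. Single-shot templates go to the first study only so no PHI string is
injected twice.

## Answer key and crosswalks

The key derives mechanically from provenance: each PHI span becomes one
`text_removed` entry, each retained span one `text_retained` entry, each
date shift one `date_shifted` entry whose action text is the date visible in
the evaluation dataset, each burn-in one `pixels_hidden` entry carrying the
rectangle (`"r0,c0,r1,c1"` — the published key format omits coordinates, but
a self-contained evaluator needs them) and the burned text. From the dataset
hierarchy come `uid_changed` entries for every study, series and instance
UID, and `tag_retained` (+ `text_notnull` for Type 1) for every
research-critical attribute, per series. Keys are CSV with a JSON-encoded
action-text column — machine-parseable while preserving the bracketed-list
appearance of the published format — and a scope-selector column is added so
keys resolve in isolation. Crosswalks are two-column CSVs whose maps must be
injective in both directions.

## The evaluator

Scopes resolve through the crosswalks (Patient via the patient map, the rest
via the UID map); a missing crosswalk row or empty resolution is reported as
`unresolvable`, deliberately distinct from `fail`, so de-identification
errors separate from bookkeeping errors. Checks are per entry with
per-instance evidence. Numerical/semantic choices:

* `text_removed` matches case-insensitively (a leaked name in any casing is
  still PHI); an absent or empty tag passes.
* `text_retained` matches verbatim — retained clinical strings must survive
  exactly.
* `date_shifted` defaults to **inferred** mode: all dated entries of one
  patient must exhibit a single common nonzero offset. This makes the tool
  usable against third-party de-identifiers that choose their own offsets
  while still enforcing interval preservation; `fixed` mode checks a supplied
  per-patient offset table instead.
* `pixels_hidden` demands a uniform region (standard deviation exactly 0)
  inside the keyed rectangle — the strictest reading of "hidden"; partial
  masking fails.
* Leakage scanning is a case-insensitive substring hunt over every text
  element of every instance, plus a burn-value probe inside keyed rectangles
  only (no OCR). The report's `overall_pass` requires zero failures and zero
  leaks.

The oracle de-identifier draws its per-patient offsets from ±[30, 365] days,
excluding any offset that would land a shifted date exactly on another keyed
PHI date string (re-introducing keyed text via a shift is itself a
de-identification failure, so the reference implementation avoids it by
construction). Its four fault flags (`skip_burnin`, `skip_private`,
`unshifted_dates`, `reuse_uids`) each break exactly one action class, which
the test suite uses to prove the evaluator localizes faults.

## What the tests do and do not show

The suite builds everything from code: a small two-modality fixture (10
images, 96x96) exercises every operation, property and the full
oracle/identity score bounds; the bundled full manifest is built once at
128x128 to verify the published composition exactly; 10,000-record cohorts
check ID uniqueness; pydicom (via the system Python) independently re-reads
files written here, confirming interoperable byte layout. Problem sizes were
chosen so the whole suite runs in about a minute on one CPU.

Because the phantoms are synthetic, passing tests demonstrate correctness of
the *benchmark machinery* — injection, bookkeeping, scoring — not that any
de-identifier will behave the same on clinical images: real headers carry
vendor idiosyncrasies, non-ASCII charsets, sequences and compressed transfer
syntaxes that are out of scope here, and real burned-in text is rendered by
modality consoles, not a bitmap font. Quantities that depend on the original
archive data — the byte size of the published collection and the audit-log
frequency counts behind the attribute catalogues — are consumed as catalogue
metadata only and never asserted.

## Known limitations

Single-frame, uncompressed, Explicit VR Little Endian only; no sequences
beyond opaque passthrough; no OCR-based pixel PHI detection (pixel checks are
rectangle-based); no RT Structure Set objects (the two `(3006,xxxx)`
attributes are catalogued as header-text injection targets only); no
statistical re-identification risk modelling. The production answer-key
schema used by the original curation programme is not public; the schema here
is a faithful, machine-resolvable extension of its published form, not a
claim of bit-compatibility.
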