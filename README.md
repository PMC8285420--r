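# deidbench

Synthetic-PHI DICOM benchmarks for evaluating medical image
de-identification.

Sharing medical images for research requires removing protected health
information (PHI) from DICOM headers, from manufacturer private attributes,
and from text burned into the pixels. Judging whether a de-identification
algorithm actually did that needs ground truth — a dataset in which every
piece of PHI is synthetic, planted at known locations, with a machine-readable
statement of what a correct de-identifier must do to each one. `deidbench`
manufactures such benchmarks entirely from code and scores any candidate
output against them. It is aimed at de-identification tool developers,
curation teams, and anyone running a de-identification challenge.

## What it does

```
manifest ──► phantom factory ──► clean dataset (PHI-free synthetic DICOM)
                                      │
identities (seeded forge) ──► injector (set_tag / delete_tag / shift_date /
                                        substitute / string_replace /
                                        annotate_img)
                                      │
                        evaluation dataset + provenance log
                                      │
                    answer key (CSV) + patient-ID / UID crosswalks
                                      │
    candidate de-identifier (yours, or the built-in oracle / identity)
                                      │
                evaluator ──► per-check report + PHI leakage scan
```

The answer key drives seven check actions per scoped tag: `tag_retained`,
`text_notnull`, `text_retained`, `text_removed`, `date_shifted` (one common
nonzero per-patient offset, inferred or fixed), `uid_changed` (validated
against the crosswalk), and `pixels_hidden` (the keyed rectangle must be a
uniform region, standard deviation 0). Leakage scanning hunts every removed
span case-insensitively across all text elements, plus a burn-value probe
inside keyed rectangles (no OCR).

Everything is deterministic in the seeds: identities are pure functions of
`(seed, patient index)`, dataset expansion uses largest-remainder allocation,
and regenerating with the same seed reproduces byte-identical files. A
minimal pure-R DICOM Part-10 reader/writer (Explicit VR Little Endian,
single-frame, unknown VRs carried opaquely) keeps the package dependency-free
beyond `jsonlite`.

## Worked example

```r
library(deidbench)

manifest <- new_manifest(data.frame(
  modality = c("CT", "MG"), patients = c(2, 1), studies = c(3, 1),
  series = c(3, 2), images = c(6, 4),
  body_parts = c("BLADDER:2;CHEST:1", "BREAST:1"),
  manufacturers = c("SIEMENS:3", "LORAD:1")))

clean <- build_dataset(manifest, seed = 3, matrix_size = 96)
clean
#> <dicom_dataset: 10 instances, 3 patients, 4 studies, 5 series>

plan <- default_plan(clean, seed = 11)      # one synthetic identity/patient
res  <- run_plan(clean, plan)               # evaluation dataset + provenance
key  <- derive_answer_key(res$provenance, res$dataset)
length(key)
#> [1] 429

oracle <- build_oracle_deid(res$dataset, key, seed = 99)
evaluate_dataset(oracle$dataset, key, oracle$patient_xwalk, oracle$uid_xwalk)
#> <evaluation_report: 429 checks (429 pass, 0 fail, 0 unresolvable), 0 leaks, overall PASS>
#>   tag_retained   pass  155  fail    0  unresolvable    0
#>   text_notnull   pass   77  fail    0  unresolvable    0
#>   text_retained  pass   48  fail    0  unresolvable    0
#>   text_removed   pass  123  fail    0  unresolvable    0
#>   date_shifted   pass    4  fail    0  unresolvable    0
#>   uid_changed    pass   19  fail    0  unresolvable    0
#>   pixels_hidden  pass    3  fail    0  unresolvable    0

idd <- identity_deid(res$dataset)           # adversarial baseline: no-op copy
evaluate_dataset(idd$dataset, key, idd$patient_xwalk, idd$uid_xwalk)
#> <evaluation_report: 429 checks (280 pass, 149 fail, 0 unresolvable), 345 leaks, overall FAIL>
#>   ...
#>   text_removed   pass    0  fail  123  unresolvable    0
#>   date_shifted   pass    0  fail    4  unresolvable    0
#>   uid_changed    pass    0  fail   19  unresolvable    0
#>   pixels_hidden  pass    0  fail    3  unresolvable    0
```

Read this as: the 429-entry key demands 123 text removals, 4 date shifts, 19
UID remaps and 3 pixel maskings, while 280 retention checks guard the
research-critical attributes. The oracle satisfies all of them with zero
residual PHI; a verbatim copy fails exactly the removal/shift/remap/mask
checks and leaks 345 PHI hits — the two ends of the score range any real
de-identifier falls between.

To score an external tool, point it at the written evaluation dataset and
feed its output (plus its crosswalks) to the evaluator:

```sh
deidbench generate    --manifest inst/extdata/manifest_benchmark.csv --out clean --seed 1
deidbench inject      --input clean --out eval --seed 1
<your de-identifier>  eval/ -> deid/ (+ patient and UID crosswalk CSVs)
deidbench evaluate    --input deid --key eval/answer_key.csv \
                      --patient-xwalk deid/patient_crosswalk.csv \
                      --uid-xwalk deid/uid_crosswalk.csv --report report.json
```

(`deidbench` is the thin Rscript in `exec/`; exit codes: 0 pass, 1 fail,
2 usage error.) The bundled `manifest_benchmark.csv` regenerates the published
benchmark composition: 1,693 images (268 CT, 150 MR, 1,203 PT, 10 DX, 4 CR,
58 MG) over 21 patients, 22 studies, 26 series.

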