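Package: deidbench
Title: Synthetic-PHI DICOM Benchmarks for Medical Image De-Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds self-contained benchmark datasets for evaluating DICOM
    de-identification software. A phantom factory expands a dataset-composition
    manifest into a clean, PHI-free synthetic DICOM collection with
    modality-correct Type 1/2 attributes; a seeded forge generates synthetic
    protected health information (patient identities, accession numbers,
    mixed clinical/PHI text); an injector applies declarative
    re-identification operations (tag edits, date shifts, text substitution,
    pixel burn-in) and logs full provenance; the provenance is distilled into
    a machine-readable answer key plus patient-ID and UID crosswalks; and an
    evaluator scores any candidate de-identified dataset against the key,
    reporting per-check results and residual PHI leakage. Includes a minimal
    pure-R DICOM Part-10 reader/writer (Explicit VR Little Endian) and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
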