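# Shared fixtures, built in code and cached for the duration of the run.
# The "small" composition keeps property tests fast: two CT patients (one
# with two studies) plus one MG patient, 96x96 phantoms.

small_manifest <- function() {
  new_manifest(data.frame(
    modality = c("CT", "MG"),
    patients = c(2L, 1L),
    studies = c(3L, 1L),
    series = c(3L, 2L),
    images = c(6L, 4L),
    body_parts = c("BLADDER:2;CHEST:1", "BREAST:1"),
    manufacturers = c("SIEMENS:3", "LORAD:1"),
    stringsAsFactors = FALSE))
}

.fixture_cache <- new.env(parent = emptyenv())

# Clean dataset -> default plan -> injected dataset + key + oracle + identity.
small_pipeline <- function() {
  if (is.null(.fixture_cache$pipe)) {
    clean <- build_dataset(small_manifest(), seed = 3, matrix_size = 96)
    plan <- default_plan(clean, seed = 11)
    res <- run_plan(clean, plan)
    key <- derive_answer_key(res$provenance, res$dataset)
    oracle <- build_oracle_deid(res$dataset, key, seed = 99)
    identity <- identity_deid(res$dataset)
    .fixture_cache$pipe <- list(
      clean = clean, plan = plan, injected = res$dataset,
      provenance = res$provenance, key = key, oracle = oracle,
      identity = identity)
  }
  .fixture_cache$pipe
}

# A fully-specified plan leaf for single-instance tests.
test_node <- function(modality = "CT", slot = 1L) {
  list(modality = modality, patient_slot = slot,
       patient_id = sprintf("PHANTOM-%03d", slot),
       study_uid = sprintf("1.2.826.0.1.3680043.10.1188.77.%d", slot),
       study_date = "20200105", body_part = "CHEST", manufacturer = "SIEMENS",
       series_uid = sprintf("1.2.826.0.1.3680043.10.1188.77.%d.1", slot),
       series_number = 1L,
       instance_uid = sprintf("1.2.826.0.1.3680043.10.1188.77.%d.1.1", slot),
       instance_number = 1L)
}

report_status <- function(report) {
  vapply(report$results, `[[`, character(1), "status")
}

report_actions <- function(report) {
  vapply(report$results, function(r) r$entry$action, character(1))
}
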