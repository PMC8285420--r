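# Phantom factory: expand a composition manifest (per-modality patient /
# study / series / image counts with body-part and manufacturer study
# assignments) into a clean, PHI-free synthetic DICOM dataset.

UID_ROOT <- "1.2.826.0.1.3680043.10.1188"

#' Read and validate a composition manifest
#'
#' The manifest CSV mirrors the published dataset-characterization table: one
#' row per modality with patient/study/series/image counts plus `LABEL:count`
#' lists (`;`-separated) assigning body parts and manufacturers to studies.
#' An optional `Total` row pins the collection totals; its patient total may
#' be smaller than the per-modality sum, in which case patient slots wrap
#' around a shared global pool (a patient imaged under two modalities).
#'
#' @param path Manifest CSV. The fixture transcribing the published
#'   composition ships as `manifest_benchmark.csv` (see [benchmark_manifest()]).
#' @return A `composition_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_manifest(df)
}

#' @rdname read_manifest
#' @export
benchmark_manifest <- function() read_manifest(pkg_extdata("manifest_benchmark.csv"))

#' @rdname read_manifest
#' @param df Data frame with manifest columns (`modality`, `patients`,
#'   `studies`, `series`, `images`, `body_parts`, `manufacturers`).
#' @export
new_manifest <- function(df) {
  need <- c("modality", "patients", "studies", "series", "images")
  if (!all(need %in% names(df))) fail_with("manifest lacks required columns")
  if (!"body_parts" %in% names(df)) df$body_parts <- ""
  if (!"manufacturers" %in% names(df)) df$manufacturers <- ""
  tot <- df[df$modality == "Total", , drop = FALSE]
  rows <- df[df$modality != "Total", , drop = FALSE]
  totals <- NULL
  if (nrow(tot) == 1L) {
    totals <- list(patients = tot$patients, studies = tot$studies,
                   series = tot$series, images = tot$images)
  }
  m <- structure(list(rows = rows, totals = totals),
                 class = "composition_manifest")
  validate_manifest(m)
  m
}

parse_label_counts <- function(txt, n_studies, what) {
  if (is.na(txt) || !nzchar(txt)) {
    return(rep("", n_studies))
  }
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.*):([0-9]+)$", parts))
  labels <- vapply(m, function(x) x[2], character(1))
  counts <- vapply(m, function(x) as.integer(x[3]), integer(1))
  if (sum(counts) != n_studies) {
    fail_with("%s counts sum to %d but the row has %d studies",
              what, sum(counts), n_studies)
  }
  # "[BLANK]" is a literal label meaning an empty Body Part Examined value
  labels[labels == "[BLANK]"] <- ""
  rep(labels, counts)
}

validate_manifest <- function(m) {
  rows <- m$rows
  if (!nrow(rows)) return(invisible(TRUE))
  bad <- setdiff(rows$modality, MODALITIES)
  if (length(bad)) fail_with("unsupported modality in manifest: %s", bad[1])
  counts <- rows[c("patients", "studies", "series", "images")]
  if (any(as.matrix(counts) <= 0) || any(as.matrix(counts) != round(as.matrix(counts)))) {
    fail_with("manifest counts must be positive integers")
  }
  ok <- rows$patients <= rows$studies & rows$studies <= rows$series &
    rows$series <= rows$images
  if (!all(ok)) {
    fail_with("manifest row %s violates patients <= studies <= series <= images",
              rows$modality[which(!ok)[1]])
  }
  for (i in seq_len(nrow(rows))) {
    parse_label_counts(rows$body_parts[i], rows$studies[i], "body-part")
    parse_label_counts(rows$manufacturers[i], rows$studies[i], "manufacturer")
  }
  if (!is.null(m$totals)) {
    for (f in c("studies", "series", "images")) {
      if (sum(rows[[f]]) != m$totals[[f]]) {
        fail_with("manifest %s sum (%d) disagrees with Total row (%d)",
                  f, sum(rows[[f]]), m$totals[[f]])
      }
    }
    if (m$totals$patients > sum(rows$patients)) {
      fail_with("Total patients exceeds the per-modality sum")
    }
  }
  invisible(TRUE)
}

#' @export
print.composition_manifest <- function(x, ...) {
  cat(sprintf("<composition_manifest: %d modalities, %d images>\n",
              nrow(x$rows), sum(x$rows$images)))
  invisible(x)
}

# Largest-remainder split of n items over k slots: earlier slots take the
# remainder, so counts are floor(n/k)+1 for the first n %% k slots.
lr_split <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + as.integer(seq_len(k) <= rem)
}

#' Expand a manifest into a hierarchy plan
#'
#' Deterministically allocates studies to patients, series to studies and
#' images to series by largest-remainder round-robin (earlier slots take the
#' remainders), assigns body parts and manufacturers to studies in manifest
#' order, and lays out the patient/study/series/instance UID hierarchy.
#' Patient slots are drawn from a global pool sized by the manifest's patient
#' total, wrapping modulo the pool when the per-modality sum exceeds it.
#'
#' @param manifest A `composition_manifest`.
#' @param seed Integer seed; folded into the generated UIDs and placeholder
#'   study dates.
#' @return A `hierarchy_plan`: list with `patients`, `studies`, `series` and
#'   `instances` data frames.
#' @export
expand_manifest <- function(manifest, seed) {
  validate_manifest(manifest)
  rows <- manifest$rows
  n_pool <- if (!is.null(manifest$totals)) manifest$totals$patients else sum(rows$patients)
  slot_cursor <- 0L
  study_gid <- 0L
  series_gid <- 0L
  studies <- list()
  series <- list()
  instances <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    body_parts <- parse_label_counts(r$body_parts, r$studies, "body-part")
    manufacturers <- parse_label_counts(r$manufacturers, r$studies, "manufacturer")
    studies_per_patient <- lr_split(r$studies, r$patients)
    series_per_study <- lr_split(r$series, r$studies)
    images_per_series <- lr_split(r$images, r$series)
    study_i <- 0L
    series_i <- 0L
    for (p in seq_len(r$patients)) {
      slot <- (slot_cursor %% n_pool) + 1L
      slot_cursor <- slot_cursor + 1L
      patient_id <- sprintf("PHANTOM-%03d", slot)
      for (s in seq_len(studies_per_patient[p])) {
        study_i <- study_i + 1L
        study_gid <- study_gid + 1L
        study_uid <- sprintf("%s.%d.2.%d", UID_ROOT, seed, study_gid)
        study_date <- fmt_date(as.Date("2020-01-01") + (study_gid %% 365L))
        studies[[length(studies) + 1L]] <- data.frame(
          modality = r$modality, patient_slot = slot, patient_id = patient_id,
          study_uid = study_uid, study_date = study_date,
          body_part = body_parts[study_i], manufacturer = manufacturers[study_i],
          stringsAsFactors = FALSE)
        for (se in seq_len(series_per_study[study_i])) {
          series_i <- series_i + 1L
          series_gid <- series_gid + 1L
          series_uid <- sprintf("%s.%d", study_uid, series_gid)
          n_img <- images_per_series[series_i]
          series[[length(series) + 1L]] <- data.frame(
            modality = r$modality, patient_slot = slot, patient_id = patient_id,
            study_uid = study_uid, series_uid = series_uid,
            series_number = se, n_images = n_img, stringsAsFactors = FALSE)
          inst_idx <- seq_len(n_img)
          instances[[length(instances) + 1L]] <- data.frame(
            modality = r$modality, patient_slot = slot, patient_id = patient_id,
            study_uid = study_uid, study_date = study_date,
            body_part = body_parts[study_i], manufacturer = manufacturers[study_i],
            series_uid = series_uid, series_number = se,
            instance_uid = sprintf("%s.%d", series_uid, inst_idx),
            instance_number = inst_idx, stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind <- function(x, template) {
    if (!length(x)) return(template)
    out <- do.call(rbind, c(x, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
  }
  empty_df <- function(cols) {
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  inst_df <- bind(instances, empty_df(c(
    "modality", "patient_slot", "patient_id", "study_uid", "study_date",
    "body_part", "manufacturer", "series_uid", "series_number",
    "instance_uid", "instance_number")))
  stud_df <- bind(studies, empty_df(c("modality", "study_uid")))
  ser_df <- bind(series, empty_df(c("modality", "series_uid")))
  pats <- unique(inst_df[c("patient_slot", "patient_id")])
  structure(list(patients = pats, studies = stud_df, series = ser_df,
                 instances = inst_df, seed = seed),
            class = "hierarchy_plan")
}

#' @export
print.hierarchy_plan <- function(x, ...) {
  cat(sprintf("<hierarchy_plan: %d patients, %d studies, %d series, %d instances>\n",
              nrow(x$patients), nrow(x$studies), nrow(x$series),
              nrow(x$instances)))
  invisible(x)
}

#' Render a deterministic phantom pixel matrix
#'
#' A smooth diagonal gradient spanning [0, 60000] plus seeded Gaussian noise,
#' clamped below the 16-bit maximum so burned-in text (written at the maximum
#' value) is always distinguishable from the anatomy stand-in.
#'
#' @param rows,cols Matrix dimensions (>= 32 so burn-in regions fit).
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation in pixel units; 0 gives the pure
#'   gradient.
#' @return An integer matrix with values in [0, 64000].
#' @export
render_phantom_pixels <- function(rows, cols, seed, noise_sd = 200) {
  if (rows < 32L || cols < 32L) {
    fail_with("phantom matrices must be at least 32x32 to host burn-in regions")
  }
  grad <- outer(seq_len(rows) - 1L, seq_len(cols) - 1L, `+`) /
    ((rows - 1L) + (cols - 1L)) * 60000
  px <- round(grad)
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, rows, cols, 101),
                       round(stats::rnorm(rows * cols, 0, noise_sd)))
    px <- px + matrix(noise, nrow = rows)
  }
  px <- pmin(pmax(px, 0), 64000)
  storage.mode(px) <- "integer"
  px
}

# Per-rule attribute value generation for one plan leaf.
profile_rule_value <- function(rule, node, ctx) {
  switch(rule,
    sop_class_uid = unname(SOP_CLASS_UIDS[node$modality]),
    sop_instance_uid = node$instance_uid,
    study_uid = node$study_uid,
    series_uid = node$series_uid,
    study_date = node$study_date,
    study_time = "120000",
    modality = node$modality,
    manufacturer = node$manufacturer,
    patient_name = sprintf("PHANTOM^%03d", node$patient_slot),
    patient_id = node$patient_id,
    birth_date = "19000101",
    sex = "O",
    body_part = node$body_part,
    study_id = sprintf("SID%04d", node$patient_slot),
    series_number = as.character(node$series_number),
    instance_number = as.character(node$instance_number),
    samples_per_pixel = 1L,
    photometric = "MONOCHROME2",
    rows = ctx$matrix_size,
    cols = ctx$matrix_size,
    bits_allocated = 16L,
    bits_stored = 16L,
    high_bit = 15L,
    pixel_representation = 0L,
    image_type = "ORIGINAL\\PRIMARY\\AXIAL",
    kvp = "120",
    presentation_intent = "FOR PRESENTATION",
    positioner_type = "MAMMOGRAPHIC",
    organ_exposed = "BREAST",
    image_position = "0\\0\\0",
    image_orientation = "1\\0\\0\\0\\1\\0",
    conversion_type = "WSD",
    empty = "",
    study_description = "PHANTOM STUDY",
    series_description = "PHANTOM SERIES",
    fail_with("unknown profile generation rule: %s", rule)
  )
}

#' Build one clean instance from a plan leaf
#'
#' Populates every Type 1 attribute of the modality profile with a valid
#' value and every Type 2 attribute with a value or an empty string, using
#' neutral non-PHI placeholders for patient-identifying fields
#' (`PHANTOM^000` style), plus phantom pixels. Conditional (1C/2C) attributes
#' are never generated.
#'
#' @param node One row of a `hierarchy_plan`'s `instances` table (as a list
#'   or single-row data frame).
#' @param seed Integer seed (drives the pixel noise).
#' @param matrix_size Square pixel matrix edge, >= 32.
#' @param profiles Profile table.
#' @return A `dicom_instance`.
#' @export
build_instance <- function(node, seed, matrix_size = 128L,
                           profiles = default_profiles()) {
  node <- as.list(node)
  if (!node$modality %in% MODALITIES) {
    fail_with("unsupported modality: %s", node$modality)
  }
  ctx <- list(matrix_size = as.integer(matrix_size))
  rows <- profile_for_modality(node$modality, profiles)
  inst <- new_instance()
  for (i in seq_len(nrow(rows))) {
    ty <- rows$type[i]
    rule <- rows$rule[i]
    if (!ty %in% c("1", "2", "3") || rule %in% c("none", "pixel_data")) next
    val <- profile_rule_value(rule, node, ctx)
    if (ty == "1" && value_is_empty(val)) {
      fail_with("Type 1 attribute %s generated empty for %s",
                rows$tag[i], node$modality)
    }
    tag <- parse_tag(rows$tag[i])
    inst <- set_element(inst, tag, val, default_vr(tag))
  }
  px <- render_phantom_pixels(ctx$matrix_size, ctx$matrix_size,
                              derive_seed(seed, node$instance_uid_hash %||%
                                            sum(utf8ToInt(node$instance_uid))))
  set_pixels(inst, px)
}

#' Generate the clean dataset for a plan
#'
#' @param plan A `hierarchy_plan` from [expand_manifest()], or a
#'   `composition_manifest` (expanded internally).
#' @param seed Integer seed.
#' @param matrix_size Square pixel matrix edge.
#' @param profiles Profile table.
#' @return A `dicom_dataset`.
#' @export
build_dataset <- function(plan, seed, matrix_size = 128L,
                          profiles = default_profiles()) {
  if (inherits(plan, "composition_manifest")) {
    plan <- expand_manifest(plan, seed)
  }
  stopifnot(inherits(plan, "hierarchy_plan"))
  leaves <- plan$instances
  insts <- vector("list", nrow(leaves))
  for (i in seq_len(nrow(leaves))) {
    insts[[i]] <- build_instance(leaves[i, ], seed, matrix_size, profiles)
  }
  new_dataset(insts)
}
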