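# Reference de-identifiers. The oracle applies exactly the transformations
# the answer key demands and must score a perfect report; the identity copy
# changes nothing and must fail every removal/shift/remap check. Single-fault
# oracle variants support fault-localization testing.

ORACLE_FAULTS <- c("skip_burnin", "skip_private", "unshifted_dates",
                   "reuse_uids")

# Draw one nonzero day offset per patient, excluding offsets that would land
# a shifted date exactly on another keyed PHI date string (shifting a date
# onto text the key demands removed would itself re-identify).
draw_shift_days <- function(key, meta, patients, seed) {
  date_spans <- unlist(lapply(key, function(e) {
    if (e$action == "text_removed") {
      e$action_text[grepl("^[0-9]{8}$", e$action_text)]
    } else character(0)
  }))
  study_patient <- stats::setNames(meta$patient_id, meta$study_uid)
  origins <- lapply(stats::setNames(nm = patients), function(p) character(0))
  for (e in key) {
    if (e$action != "date_shifted") next
    p <- unname(study_patient[e$scope_selector])
    if (!is.na(p)) origins[[p]] <- c(origins[[p]], e$action_text[1])
  }
  out <- stats::setNames(integer(length(patients)), patients)
  pool <- c(-365:-30, 30:365)
  for (i in seq_along(patients)) {
    orig <- origins[[patients[i]]]
    forbidden <- integer(0)
    if (length(orig) && length(date_spans)) {
      forbidden <- as.integer(outer(as.Date(date_spans, "%Y%m%d"),
                                    as.Date(orig, "%Y%m%d"), `-`))
    }
    allowed <- setdiff(pool, forbidden)
    out[i] <- with_seed(derive_seed(seed, 37, i), sample(allowed, 1L))
  }
  out
}

# Remove a span from a text value, case-insensitively, and tidy whitespace.
surgically_remove <- function(value, span) {
  out <- gsub(span, "", value, fixed = TRUE)
  if (identical(out, value)) {
    # fall back to case-insensitive literal removal
    hits <- gregexpr(tolower(span), tolower(value), fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      for (h in rev(hits)) {
        value <- paste0(substr(value, 1L, h - 1L),
                        substr(value, h + nchar(span), nchar(value)))
      }
      out <- value
    }
  }
  squish(out)
}

#' Oracle de-identification of an evaluation dataset
#'
#' Builds the reference de-identified dataset: every keyed PHI span is
#' surgically removed from its tag (retained text survives), every keyed
#' burn-in rectangle is masked to a uniform zero, every date attribute of a
#' patient is shifted by one freshly drawn nonzero per-patient offset, and
#' patient IDs and study/series/instance UIDs are remapped to fresh values.
#' Evaluating the output against the same key scores a full pass with zero
#' leaks. Fault flags deliberately skip one transformation class for
#' fault-localization tests: `"skip_burnin"` leaves rectangles unmasked,
#' `"skip_private"` skips removal for the first keyed private attribute,
#' `"unshifted_dates"` copies dates verbatim, `"reuse_uids"` keeps original
#' UIDs.
#'
#' @param dataset The injected evaluation `dicom_dataset`.
#' @param key Answer key derived from the injection provenance.
#' @param seed Integer seed for offsets and fresh identifiers.
#' @param faults Character vector of fault flags (default none).
#' @return List: `dataset`, `patient_xwalk`, `uid_xwalk`, `shift_table`.
#' @export
build_oracle_deid <- function(dataset, key, seed, faults = character(0)) {
  bad <- setdiff(faults, ORACLE_FAULTS)
  if (length(bad)) fail_with("unknown oracle fault flag: %s", bad[1])
  meta <- dataset$meta
  patients <- unique(meta$patient_id)
  patient_xwalk <- stats::setNames(sprintf("DEID-P%03d", seq_along(patients)),
                                   patients)
  uids <- unique(c(meta$study_uid, meta$series_uid, meta$instance_uid))
  uid_xwalk <- if ("reuse_uids" %in% faults) {
    stats::setNames(uids, uids)
  } else {
    stats::setNames(sprintf("%s.%d.9.%d", UID_ROOT, seed %% 100000L,
                            seq_along(uids)), uids)
  }
  shift_days <- if ("unshifted_dates" %in% faults) {
    stats::setNames(rep(0L, length(patients)), patients)
  } else {
    draw_shift_days(key, meta, patients, seed)
  }
  skip_private_tag <- NULL
  if ("skip_private" %in% faults) {
    priv <- Filter(function(e) {
      e$action == "text_removed" && !is.na(e$tag) &&
        is_private_tag(parse_tag(e$tag))
    }, key)
    if (length(priv)) skip_private_tag <- priv[[1]]$tag
  }

  # pass 1: span removals and pixel masking, resolved on original identities
  for (entry in key) {
    uids_in <- resolve_scope(entry, dataset,
                             stats::setNames(patients, patients),
                             stats::setNames(uids, uids))
    if (is.null(uids_in)) next
    if (entry$action == "text_removed") {
      if (!is.null(skip_private_tag) && identical(entry$tag, skip_private_tag)) next
      tag <- parse_tag(entry$tag)
      for (u in uids_in) {
        inst <- dataset$instances[[u]]
        el <- get_element(inst, tag)
        if (is.null(el) || !is.character(el$value) || !nzchar(el$value)) next
        newval <- el$value
        for (s in entry$action_text) newval <- surgically_remove(newval, s)
        dataset$instances[[u]] <- set_element(inst, tag, newval, el$vr)
      }
    } else if (entry$action == "pixels_hidden" && !"skip_burnin" %in% faults) {
      rect <- as.integer(strsplit(entry$action_text[1], ",")[[1]])
      for (u in uids_in) {
        inst <- dataset$instances[[u]]
        px <- inst_pixels(inst)
        if (is.null(px)) next
        px[(rect[1] + 1L):rect[3], (rect[2] + 1L):rect[4]] <- 0L
        dataset$instances[[u]] <- set_pixels(inst, px)
      }
    }
  }

  # original (pre-surgery) patient identity per instance; pass 1 may have
  # emptied the Patient ID element itself
  orig_pid <- stats::setNames(meta$patient_id, meta$instance_uid)

  # pass 2: per-patient date shifting of every remaining dated attribute
  for (u in names(dataset$instances)) {
    inst <- dataset$instances[[u]]
    days <- shift_days[[orig_pid[[u]]]]
    if (is.null(days) || days == 0L) next
    for (k in names(inst$elements)) {
      el <- inst$elements[[k]]
      if (el$vr == "DA" && is.character(el$value) && nzchar(el$value) &&
          date_is_valid(el$value)) {
        inst$elements[[k]]$value <- shift_date(el$value, days)
      }
    }
    dataset$instances[[u]] <- inst
  }

  # pass 3: remap patient IDs and UIDs
  pid_tag <- tag_path(0x0010, 0x0020)
  uid_tags <- list(tag_path(0x0020, 0x000D), tag_path(0x0020, 0x000E),
                   tag_path(0x0008, 0x0018))
  for (u in names(dataset$instances)) {
    inst <- dataset$instances[[u]]
    old_pid <- orig_pid[[u]]
    if (!is.null(old_pid) && old_pid %in% names(patient_xwalk)) {
      inst <- set_element(inst, pid_tag, unname(patient_xwalk[old_pid]), "LO")
    }
    for (tg in uid_tags) {
      v <- get_value(inst, tg)
      if (!is.null(v) && v %in% names(uid_xwalk)) {
        inst <- set_element(inst, tg, unname(uid_xwalk[v]), "UI")
      }
    }
    dataset$instances[[u]] <- inst
  }
  dataset <- refresh_meta(dataset)
  names(dataset$instances) <- dataset$meta$instance_uid

  list(dataset = dataset, patient_xwalk = patient_xwalk, uid_xwalk = uid_xwalk,
       shift_table = data.frame(patient = patients,
                                days = unname(shift_days[patients]),
                                stringsAsFactors = FALSE))
}

#' Identity "de-identifier"
#'
#' Copies the dataset unchanged and emits crosswalks mapping every patient ID
#' and UID to itself — the adversarial baseline that must fail every
#' `text_removed`, `date_shifted`, `uid_changed` and `pixels_hidden` check
#' while passing every retention check.
#'
#' @param dataset The evaluation `dicom_dataset`.
#' @return List: `dataset`, `patient_xwalk`, `uid_xwalk`, `shift_table`.
#' @export
identity_deid <- function(dataset) {
  meta <- dataset$meta
  patients <- unique(meta$patient_id)
  uids <- unique(c(meta$study_uid, meta$series_uid, meta$instance_uid))
  list(dataset = dataset,
       patient_xwalk = stats::setNames(patients, patients),
       uid_xwalk = stats::setNames(uids, uids),
       shift_table = data.frame(patient = patients, days = 0L,
                                stringsAsFactors = FALSE))
}
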