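# Evaluator: scores a candidate de-identified dataset against an answer key
# and crosswalks. Failures are results, not errors; entries whose scope
# cannot be resolved through the crosswalks are reported as `unresolvable`,
# keeping bookkeeping problems distinct from de-identification problems.

#' Resolve an answer-key entry's scope to candidate instances
#'
#' Patient scopes map the original patient ID through the patient crosswalk
#' and select instances carrying the new Patient ID; Study/Series/Instance
#' scopes map the original UID through the UID crosswalk. An empty result or
#' a missing crosswalk row is unresolvable (`NULL`).
#'
#' @param entry An [answer_key_entry].
#' @param dataset Candidate `dicom_dataset`.
#' @param patient_xwalk,uid_xwalk Named-vector crosswalks (old -> new).
#' @return Character vector of instance UID keys into `dataset$instances`,
#'   or `NULL` when unresolvable.
#' @export
resolve_scope <- function(entry, dataset, patient_xwalk, uid_xwalk) {
  meta <- dataset$meta
  sel <- entry$scope_selector
  if (entry$scope == "Patient") {
    new_pid <- unname(patient_xwalk[sel])
    if (is.na(new_pid)) return(NULL)
    out <- meta$instance_uid[meta$patient_id == new_pid]
  } else {
    new_uid <- unname(uid_xwalk[sel])
    if (is.na(new_uid)) return(NULL)
    col <- switch(entry$scope, Study = "study_uid", Series = "series_uid",
                  Instance = "instance_uid")
    out <- meta$instance_uid[meta[[col]] == new_uid]
  }
  if (!length(out)) NULL else out
}

check_result <- function(entry, status, evidence = NULL) {
  structure(list(entry = entry, status = status, evidence = evidence),
            class = "check_result")
}

entry_values <- function(entry, dataset, uids) {
  tag <- parse_tag(entry$tag)
  if (is.null(tag$creator)) {
    key <- tag_key(tag$group, tag$element)
    return(lapply(uids, function(u) dataset$instances[[u]]$elements[[key]]))
  }
  lapply(uids, function(u) get_element(dataset$instances[[u]], tag))
}

#' Check one answer-key entry
#'
#' Applies the action semantics: `tag_retained` requires the tag in every
#' scoped instance; `text_notnull` a non-empty value; `text_retained` every
#' action text verbatim in the value; `text_removed` no action text in the
#' value in any casing (an absent or empty tag passes); `date_shifted` that
#' the value equals the original shifted by the expected nonzero offset;
#' `uid_changed` a valid UID that differs from the original and matches the
#' crosswalk; `pixels_hidden` a uniform pixel region (standard deviation 0)
#' inside the keyed rectangle.
#'
#' @param entry An [answer_key_entry].
#' @param dataset Candidate dataset.
#' @param uids Instances from [resolve_scope()].
#' @param options List: `uid_xwalk` (for `uid_changed`) and `expected_days`
#'   (signed integer day offset for `date_shifted`, `NA` when no consistent
#'   offset exists).
#' @return A `check_result` with status `pass`, `fail` or `unresolvable`.
#' @export
check_entry <- function(entry, dataset, uids, options = list()) {
  if (is.null(uids) || !length(uids)) {
    return(check_result(entry, "unresolvable",
                        sprintf("scope %s '%s' resolves to no instances",
                                entry$scope, entry$scope_selector)))
  }
  act <- entry$action
  if (act == "pixels_hidden") {
    rect <- as.integer(strsplit(entry$action_text[1], ",")[[1]])
    for (u in uids) {
      px <- inst_pixels(dataset$instances[[u]])
      if (is.null(px) || rect[3] > nrow(px) || rect[4] > ncol(px)) {
        return(check_result(entry, "fail",
                            sprintf("instance %s: missing pixels or rect out of bounds", u)))
      }
      region <- px[(rect[1] + 1L):rect[3], (rect[2] + 1L):rect[4]]
      if (stats::sd(as.numeric(region)) > 0) {
        return(check_result(entry, "fail",
                            sprintf("instance %s: pixels in rect %s are not uniform (sd=%.1f)",
                                    u, entry$action_text[1],
                                    stats::sd(as.numeric(region)))))
      }
    }
    return(check_result(entry, "pass"))
  }
  els <- entry_values(entry, dataset, uids)
  if (act == "tag_retained") {
    miss <- uids[vapply(els, is.null, logical(1))]
    if (length(miss)) {
      return(check_result(entry, "fail",
                          sprintf("tag absent in instance %s", miss[1])))
    }
    return(check_result(entry, "pass"))
  }
  if (act == "text_notnull") {
    for (i in seq_along(els)) {
      if (is.null(els[[i]]) || value_is_empty(els[[i]]$value)) {
        return(check_result(entry, "fail",
                            sprintf("value null or empty in instance %s", uids[i])))
      }
    }
    return(check_result(entry, "pass"))
  }
  if (act == "text_retained") {
    for (i in seq_along(els)) {
      val <- if (is.null(els[[i]])) "" else as.character(els[[i]]$value %||% "")
      for (s in entry$action_text) {
        if (!grepl(s, val, fixed = TRUE)) {
          return(check_result(entry, "fail",
                              sprintf("'%s' not retained in instance %s (value '%s')",
                                      s, uids[i], val)))
        }
      }
    }
    return(check_result(entry, "pass"))
  }
  if (act == "text_removed") {
    for (i in seq_along(els)) {
      if (is.null(els[[i]])) next  # absence satisfies removal
      val <- els[[i]]$value
      if (!is.character(val) || !nzchar(val)) next
      for (s in entry$action_text) {
        if (grepl(tolower(s), tolower(val), fixed = TRUE)) {
          return(check_result(entry, "fail",
                              sprintf("'%s' still present in instance %s (value '%s')",
                                      s, uids[i], val)))
        }
      }
    }
    return(check_result(entry, "pass"))
  }
  if (act == "date_shifted") {
    days <- options$expected_days
    if (is.null(days) || is.na(days)) {
      return(check_result(entry, "fail",
                          "no consistent nonzero date offset for this patient"))
    }
    expected <- shift_date(entry$action_text[1], days)
    for (i in seq_along(els)) {
      val <- if (is.null(els[[i]])) NULL else els[[i]]$value
      if (is.null(val) || !identical(val, expected)) {
        return(check_result(entry, "fail",
                            sprintf("instance %s: date '%s' != expected shift of '%s' by %+d days",
                                    uids[i], val %||% "<absent>",
                                    entry$action_text[1], days)))
      }
    }
    if (days == 0L) {
      return(check_result(entry, "fail", "date offset is zero: dates were not shifted"))
    }
    return(check_result(entry, "pass"))
  }
  if (act == "uid_changed") {
    original <- entry$action_text[1]
    mapped <- unname(options$uid_xwalk[original])
    if (is.na(mapped)) {
      return(check_result(entry, "unresolvable",
                          sprintf("UID %s missing from crosswalk", original)))
    }
    for (i in seq_along(els)) {
      val <- if (is.null(els[[i]])) NULL else els[[i]]$value
      if (is.null(val) || !uid_is_valid(val) || identical(val, original) ||
          !identical(val, mapped)) {
        return(check_result(entry, "fail",
                            sprintf("instance %s: UID '%s' (expected new UID '%s', original '%s')",
                                    uids[i], val %||% "<absent>", mapped, original)))
      }
    }
    return(check_result(entry, "pass"))
  }
  fail_with("unknown action %s", act)
}

# Per-patient inferred date offsets: for each original patient, collect the
# offsets between keyed original dates and candidate values; a single common
# nonzero offset is required.
infer_date_offsets <- function(key, dataset, patient_xwalk, uid_xwalk) {
  # map each date entry to its original patient via the study -> patient
  # relation of the candidate dataset
  meta <- dataset$meta
  offs <- list()
  for (entry in key) {
    if (entry$action != "date_shifted") next
    uids <- resolve_scope(entry, dataset, patient_xwalk, uid_xwalk)
    if (is.null(uids)) next
    pid <- meta$patient_id[match(uids[1], meta$instance_uid)]
    vals <- vapply(uids, function(u) {
      v <- get_value(dataset$instances[[u]], parse_tag(entry$tag))
      if (is.null(v)) NA_character_ else v
    }, character(1))
    d <- rep(NA_integer_, length(vals))
    ok <- !is.na(vals) & vapply(vals, date_is_valid, logical(1))
    d[ok] <- as.integer(as.Date(vals[ok], "%Y%m%d") -
                          as.Date(entry$action_text[1], "%Y%m%d"))
    offs[[pid]] <- c(offs[[pid]], d)
  }
  vapply(offs, function(d) {
    if (any(is.na(d)) || length(unique(d)) != 1L) NA_integer_ else d[1]
  }, integer(1))
}

#' Scan a dataset for PHI leakage
#'
#' Case-insensitive substring search for each PHI span over every text-VR
#' element of every instance. Pixel leakage is checked only inside the answer
#' key's burn-in rectangles (no OCR): a rectangle still containing a pixel at
#' the burn value leaks its text.
#'
#' @param dataset Candidate `dicom_dataset`.
#' @param phi_spans Character vector of PHI strings to hunt for.
#' @param key Optional answer key supplying `pixels_hidden` rectangles.
#' @param uid_xwalk UID crosswalk used to locate keyed instances in the
#'   candidate dataset (identity when omitted).
#' @return Data frame of leaks: `instance_uid`, `location` (tag notation or
#'   `"pixels"`), `phi`.
#' @export
scan_leakage <- function(dataset, phi_spans, key = NULL, uid_xwalk = NULL) {
  leaks <- list()
  texts <- list()
  for (u in names(dataset$instances)) {
    inst <- dataset$instances[[u]]
    for (el in inst$elements) {
      if (is_text_vr(el$vr) && is.character(el$value) && nzchar(el$value)) {
        texts[[length(texts) + 1L]] <- c(u, sprintf("(%04x,%04x)", el$group,
                                                    el$element), el$value)
      }
    }
  }
  if (length(texts)) {
    tab <- do.call(rbind, texts)
    low <- tolower(tab[, 3])
    for (s in unique(phi_spans)) {
      if (!nzchar(s)) next
      hit <- grepl(tolower(s), low, fixed = TRUE)
      if (any(hit)) {
        leaks[[length(leaks) + 1L]] <- data.frame(
          instance_uid = tab[hit, 1], location = tab[hit, 2], phi = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(key)) {
    for (entry in key) {
      if (entry$action != "pixels_hidden") next
      orig <- entry$scope_selector
      target <- if (is.null(uid_xwalk)) orig else unname(uid_xwalk[orig])
      if (is.na(target) || !target %in% names(dataset$instances)) next
      px <- inst_pixels(dataset$instances[[target]])
      if (is.null(px)) next
      rect <- as.integer(strsplit(entry$action_text[1], ",")[[1]])
      if (rect[3] > nrow(px) || rect[4] > ncol(px)) next
      region <- px[(rect[1] + 1L):rect[3], (rect[2] + 1L):rect[4]]
      if (any(region == BURN_VALUE)) {
        leaks[[length(leaks) + 1L]] <- data.frame(
          instance_uid = target, location = "pixels",
          phi = paste(entry$action_text[-1], collapse = " "),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(leaks)) {
    return(data.frame(instance_uid = character(0), location = character(0),
                      phi = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, leaks)
  rownames(out) <- NULL
  out
}

# PHI spans an answer key implies for leakage scanning: everything that must
# be removed from headers.
key_phi_spans <- function(key) {
  unlist(lapply(key, function(e) {
    if (e$action == "text_removed") e$action_text else character(0)
  }))
}

#' Evaluate a candidate dataset against an answer key
#'
#' Resolves and checks every key entry, infers (or takes) the per-patient
#' date offset, scans for residual PHI leakage, and aggregates everything
#' into an evaluation report.
#'
#' @param dataset Candidate `dicom_dataset`.
#' @param key Answer key (list of entries).
#' @param patient_xwalk,uid_xwalk Crosswalks (old -> new).
#' @param shift_mode `"infer"` (one common nonzero offset per patient,
#'   inferred from the dated entries) or `"fixed"` (offsets supplied).
#' @param shift_table For `"fixed"`: data frame `patient` (original patient
#'   ID), `days`.
#' @return An `evaluation_report`: list with `results` (one `check_result`
#'   per entry), `per_action_counts`, `leaks`, `overall_pass`.
#' @export
evaluate_dataset <- function(dataset, key, patient_xwalk, uid_xwalk,
                             shift_mode = c("infer", "fixed"),
                             shift_table = NULL) {
  shift_mode <- match.arg(shift_mode)
  meta <- dataset$meta
  if (shift_mode == "infer") {
    offsets <- infer_date_offsets(key, dataset, patient_xwalk, uid_xwalk)
  } else {
    if (is.null(shift_table)) fail_with("fixed shift mode needs a shift table")
    offsets <- stats::setNames(as.integer(shift_table$days),
                               unname(patient_xwalk[shift_table$patient]))
  }
  results <- vector("list", length(key))
  for (i in seq_along(key)) {
    entry <- key[[i]]
    uids <- resolve_scope(entry, dataset, patient_xwalk, uid_xwalk)
    opts <- list(uid_xwalk = uid_xwalk)
    if (entry$action == "date_shifted" && !is.null(uids)) {
      pid <- meta$patient_id[match(uids[1], meta$instance_uid)]
      opts$expected_days <- offsets[pid]
      if (is.null(opts$expected_days)) opts$expected_days <- NA_integer_
    }
    results[[i]] <- check_entry(entry, dataset, uids, opts)
  }
  leaks <- scan_leakage(dataset, key_phi_spans(key), key, uid_xwalk)
  summarize_results(results, leaks)
}

#' Aggregate check results into a report
#'
#' @param results List of `check_result`s.
#' @param leaks Leak data frame from [scan_leakage()].
#' @return An `evaluation_report` whose per-action counts sum to the number
#'   of key entries and whose `overall_pass` is true iff there are zero
#'   failures and zero leaks (unresolvable entries are reported separately as
#'   bookkeeping problems).
#' @export
summarize_results <- function(results, leaks) {
  actions <- vapply(results, function(r) r$entry$action, character(1))
  status <- vapply(results, `[[`, character(1), "status")
  counts <- lapply(stats::setNames(nm = ACTION_KINDS), function(a) {
    c(pass = sum(actions == a & status == "pass"),
      fail = sum(actions == a & status == "fail"),
      unresolvable = sum(actions == a & status == "unresolvable"))
  })
  structure(list(results = results, per_action_counts = counts, leaks = leaks,
                 overall_pass = !any(status == "fail") && nrow(leaks) == 0L),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  status <- vapply(x$results, `[[`, character(1), "status")
  cat(sprintf("<evaluation_report: %d checks (%d pass, %d fail, %d unresolvable), %d leaks, overall %s>\n",
              length(x$results), sum(status == "pass"), sum(status == "fail"),
              sum(status == "unresolvable"), nrow(x$leaks),
              if (x$overall_pass) "PASS" else "FAIL"))
  for (a in names(x$per_action_counts)) {
    ct <- x$per_action_counts[[a]]
    if (sum(ct) > 0) {
      cat(sprintf("  %-14s pass %4d  fail %4d  unresolvable %4d\n", a,
                  ct["pass"], ct["fail"], ct["unresolvable"]))
    }
  }
  invisible(x)
}

#' Report to plain-list form (for JSON serialization)
#'
#' @param report An `evaluation_report`.
#' @return A list safe to pass to [jsonlite::write_json()].
#' @export
report_to_list <- function(report) {
  list(
    overall_pass = report$overall_pass,
    per_action_counts = lapply(report$per_action_counts, as.list),
    n_checks = length(report$results),
    n_leaks = nrow(report$leaks),
    leaks = report$leaks,
    entries = lapply(report$results, function(r) {
      list(scope = r$entry$scope, selector = r$entry$scope_selector,
           tag = r$entry$tag, action = r$entry$action, status = r$status,
           evidence = r$evidence)
    })
  )
}
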