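# Injector: applies declarative re-identification operations to a clean
# dataset, producing the PHI-seeded evaluation dataset plus a full
# provenance log. Six operation kinds are supported: set_tag, delete_tag,
# shift_date, substitute, string_replace, annotate_img.

OPERATION_KINDS <- c("set_tag", "delete_tag", "shift_date", "substitute",
                     "string_replace", "annotate_img")
SCOPE_KINDS <- c("Collection", "Patient", "Study", "Series", "Instance")
BURN_VALUE <- 65535L

#' Injection directives
#'
#' A directive names a scope (`Collection`, `Patient`, `Study`, `Series`,
#' `Instance`), the identifier of the scoped node, an operation kind and its
#' parameters: `value` (+ optional `phi_spans` / `retained_spans`) for
#' `set_tag`/`substitute`; `days` for `shift_date`; `old`/`new` for
#' `string_replace`; `text`, `rect` (`c(r0, c0, r1, c1)`, 0-based half-open
#' row/col) and optional `scale` for `annotate_img`.
#'
#' @param scope Scope kind.
#' @param selector Identifier of the scoped node (`""` for Collection).
#' @param op Operation kind.
#' @param tag Tag-notation string (absent for `annotate_img`).
#' @param params Named list of operation parameters.
#' @return An `injection_directive`.
#' @export
injection_directive <- function(scope, selector, op, tag = NULL, params = list()) {
  scope <- match.arg(scope, SCOPE_KINDS)
  op <- match.arg(op, OPERATION_KINDS)
  if (op != "annotate_img") {
    if (is.null(tag)) fail_with("operation %s requires a tag", op)
    parse_tag(tag)  # eager syntax check
  }
  if (op == "annotate_img") {
    r <- params$rect
    if (is.null(r) || length(r) != 4L || !(r[1] < r[3] && r[2] < r[4]) ||
        any(r < 0)) {
      fail_with("annotate_img requires rect c(r0, c0, r1, c1) with r0 < r1, c0 < c1")
    }
  }
  structure(list(scope = scope, selector = as.character(selector), op = op,
                 tag = tag, params = params),
            class = "injection_directive")
}

# Instance UIDs selected by a directive's scope on the current dataset.
scope_instances <- function(dataset, scope, selector) {
  meta <- dataset$meta
  switch(scope,
    Collection = meta$instance_uid,
    Patient = meta$instance_uid[meta$patient_id == selector],
    Study = meta$instance_uid[meta$study_uid == selector],
    Series = meta$instance_uid[meta$series_uid == selector],
    Instance = meta$instance_uid[meta$instance_uid == selector]
  )
}

new_applied_op <- function(directive, affected, before = NULL, after = NULL,
                           phi_spans = character(0),
                           retained_spans = character(0), skipped = character(0),
                           n_replacements = NA_integer_) {
  structure(list(directive = directive, affected_instances = affected,
                 before_value = before, after_value = after,
                 phi_spans = phi_spans, retained_spans = retained_spans,
                 skipped_instances = skipped, n_replacements = n_replacements,
                 final_selector = directive$selector),
            class = "applied_operation")
}

op_spans <- function(params) {
  list(phi = as.character(params$phi_spans %||% character(0)),
       retained = as.character(params$retained_spans %||% character(0)))
}

#' Apply a single re-identification operation
#'
#' Each `apply_*` function edits every instance in the directive's scope and
#' returns `list(dataset, op)` where `op` is the provenance record. `set_tag`
#' creates or overwrites (auto-reserving private creator blocks);
#' `delete_tag` removes the tag (refusing Type 1 attributes of the
#' instance's profile); `shift_date` offsets a DA value; `substitute` only
#' overwrites existing non-empty values and records skipped instances;
#' `string_replace` rewrites occurrences of a substring; `annotate_img`
#' burns glyph pixels at the maximum pixel value inside a rectangle.
#'
#' @param dataset A `dicom_dataset`.
#' @param directive An [injection_directive].
#' @return `list(dataset = <modified dataset>, op = <applied_operation>)`.
#' @export
apply_set_tag <- function(dataset, directive) {
  tag <- parse_tag(directive$tag)
  vr <- directive$params$vr %||% default_vr(tag)
  value <- directive$params$value
  validate_vr_value(vr, value)
  uids <- scope_instances(dataset, directive$scope, directive$selector)
  before <- NULL
  for (u in uids) {
    if (is.null(before)) before <- get_value(dataset$instances[[u]], tag)
    dataset$instances[[u]] <- set_element(dataset$instances[[u]], tag, value, vr)
  }
  sp <- op_spans(directive$params)
  list(dataset = dataset,
       op = new_applied_op(directive, uids, before, value, sp$phi, sp$retained))
}

#' @rdname apply_set_tag
#' @export
apply_delete_tag <- function(dataset, directive) {
  tag <- parse_tag(directive$tag)
  uids <- scope_instances(dataset, directive$scope, directive$selector)
  affected <- character(0)
  before <- NULL
  for (u in uids) {
    inst <- dataset$instances[[u]]
    el <- get_element(inst, tag)
    if (is.null(el)) next
    ty <- attribute_type(inst_modality(inst), tag)
    if (ty == "T1") {
      fail_with("refusing to delete Type 1 attribute %s: file would become invalid",
                directive$tag)
    }
    if (is.null(before)) before <- el$value
    dataset$instances[[u]] <- delete_element(inst, tag)
    affected <- c(affected, u)
  }
  list(dataset = dataset,
       op = new_applied_op(directive, affected, before, NULL,
                           skipped = setdiff(uids, affected)))
}

#' @rdname apply_set_tag
#' @export
apply_shift_date <- function(dataset, directive) {
  tag <- parse_tag(directive$tag)
  days <- directive$params$days
  if (is.null(days)) fail_with("shift_date requires params$days")
  uids <- scope_instances(dataset, directive$scope, directive$selector)
  before <- NULL
  after <- NULL
  for (u in uids) {
    inst <- dataset$instances[[u]]
    el <- get_element(inst, tag)
    if (is.null(el)) fail_with("shift_date target %s absent in instance %s",
                               directive$tag, u)
    if (el$vr != "DA") fail_with("shift_date requires a DA attribute, got %s", el$vr)
    shifted <- shift_date(el$value, days)
    if (is.null(before)) before <- el$value
    after <- shifted
    dataset$instances[[u]] <- set_element(inst, tag, shifted, "DA")
  }
  # the date visible in the evaluation dataset is the PHI the key tracks
  list(dataset = dataset,
       op = new_applied_op(directive, uids, before, after,
                           phi_spans = if (is.null(after)) character(0) else after))
}

#' @rdname apply_set_tag
#' @export
apply_substitute <- function(dataset, directive) {
  tag <- parse_tag(directive$tag)
  vr <- directive$params$vr %||% default_vr(tag)
  value <- directive$params$value
  validate_vr_value(vr, value)
  uids <- scope_instances(dataset, directive$scope, directive$selector)
  affected <- character(0)
  skipped <- character(0)
  before <- NULL
  for (u in uids) {
    inst <- dataset$instances[[u]]
    el <- get_element(inst, tag)
    if (is.null(el) || value_is_empty(el$value)) {
      skipped <- c(skipped, u)
      next
    }
    if (is.null(before)) before <- el$value
    dataset$instances[[u]] <- set_element(inst, tag, value, vr)
    affected <- c(affected, u)
  }
  sp <- op_spans(directive$params)
  list(dataset = dataset,
       op = new_applied_op(directive, affected, before,
                           if (length(affected)) value else NULL,
                           if (length(affected)) sp$phi else character(0),
                           if (length(affected)) sp$retained else character(0),
                           skipped = skipped))
}

#' @rdname apply_set_tag
#' @export
apply_string_replace <- function(dataset, directive) {
  tag <- parse_tag(directive$tag)
  old <- directive$params$old
  new <- directive$params$new
  if (is.null(old) || is.null(new)) fail_with("string_replace requires params old/new")
  uids <- scope_instances(dataset, directive$scope, directive$selector)
  n_repl <- 0L
  affected <- character(0)
  before <- NULL
  after <- NULL
  for (u in uids) {
    inst <- dataset$instances[[u]]
    el <- get_element(inst, tag)
    if (is.null(el) || !is.character(el$value)) next
    hits <- if (nzchar(old)) {
      h <- gregexpr(old, el$value, fixed = TRUE)[[1]]
      if (h[1] == -1L) 0L else length(h)
    } else 0L
    n_repl <- n_repl + hits
    if (is.null(before)) before <- el$value
    newval <- gsub(old, new, el$value, fixed = TRUE)
    after <- newval
    dataset$instances[[u]] <- set_element(inst, tag, newval, el$vr)
    affected <- c(affected, u)
  }
  sp <- op_spans(directive$params)
  list(dataset = dataset,
       op = new_applied_op(directive, affected, before, after,
                           if (n_repl > 0L) sp$phi else character(0),
                           if (n_repl > 0L) sp$retained else character(0),
                           n_replacements = n_repl))
}

#' @rdname apply_set_tag
#' @export
apply_annotate_img <- function(dataset, directive) {
  text <- directive$params$text %||% ""
  rect <- as.integer(directive$params$rect)
  scale <- as.integer(directive$params$scale %||% 1L)
  uids <- scope_instances(dataset, directive$scope, directive$selector)
  for (u in uids) {
    inst <- dataset$instances[[u]]
    px <- inst_pixels(inst)
    if (is.null(px)) fail_with("instance %s has no pixel data", u)
    if (rect[3] > nrow(px) || rect[4] > ncol(px)) {
      fail_with("burn-in rect exceeds the %dx%d pixel matrix", nrow(px), ncol(px))
    }
    if (nzchar(text)) {
      mask <- render_text_mask(text, rect[3] - rect[1], rect[4] - rect[2], scale)
      sub <- px[(rect[1] + 1L):rect[3], (rect[2] + 1L):rect[4], drop = FALSE]
      sub[mask] <- BURN_VALUE
      px[(rect[1] + 1L):rect[3], (rect[2] + 1L):rect[4]] <- sub
      dataset$instances[[u]] <- set_pixels(inst, px)
    }
  }
  list(dataset = dataset,
       op = new_applied_op(directive, uids,
                           phi_spans = if (nzchar(text)) text else character(0)))
}

OP_DISPATCH <- list(set_tag = apply_set_tag, delete_tag = apply_delete_tag,
                    shift_date = apply_shift_date, substitute = apply_substitute,
                    string_replace = apply_string_replace,
                    annotate_img = apply_annotate_img)

#' Run an injection plan
#'
#' Applies directives in plan order, refreshing dataset metadata after each
#' operation (so later directives can select by values earlier ones wrote),
#' and returns the evaluation dataset with the complete provenance log. For
#' fixed inputs the result is fully deterministic. The first failing
#' directive aborts with a positional error.
#'
#' @param dataset The clean `dicom_dataset`.
#' @param plan An `injection_plan` from [default_plan()], or a bare list of
#'   [injection_directive]s.
#' @return `list(dataset, provenance)`; `provenance` is a list of
#'   `applied_operation` records with final scope selectors resolved against
#'   the injected dataset.
#' @export
run_plan <- function(dataset, plan) {
  directives <- if (inherits(plan, "injection_plan")) plan$directives else plan
  provenance <- vector("list", length(directives))
  for (i in seq_along(directives)) {
    d <- directives[[i]]
    if (!length(scope_instances(dataset, d$scope, d$selector)) &&
        d$op != "substitute") {
      fail_with("plan directive %d: scope selector %s (%s) resolves to no instances",
                i, d$selector, d$scope)
    }
    res <- tryCatch(OP_DISPATCH[[d$op]](dataset, d), error = function(e) {
      fail_with("plan directive %d (%s on %s): %s", i, d$op,
                d$tag %||% "pixels", conditionMessage(e))
    })
    dataset <- res$dataset
    # identity attributes feed scope resolution: refresh the metadata table
    # only when one of them may have changed
    if (!is.null(d$tag) &&
        format_tag(parse_tag(d$tag)) %in%
          c("(0010,0020)", "(0020,000d)", "(0020,000e)", "(0008,0018)",
            "(0008,0060)")) {
      dataset <- refresh_meta(dataset)
    }
    provenance[[i]] <- res$op
  }
  # resolve final selectors: Patient-scope selectors must name the patient as
  # identified in the finished evaluation dataset
  for (i in seq_along(provenance)) {
    op <- provenance[[i]]
    if (op$directive$scope == "Patient" && length(op$affected_instances)) {
      op$final_selector <-
        inst_patient_id(dataset$instances[[op$affected_instances[1]]])
      provenance[[i]] <- op
    }
  }
  list(dataset = dataset, provenance = provenance)
}

# --- default plan ---------------------------------------------------------

#' Build the default injection plan for a clean dataset
#'
#' One synthetic identity per patient ([make_phi_corpus()]), injected as:
#' patient name / ID / birth date at Patient scope; accession number and the
#' per-study physician pair at every study; the study date shifted to the
#' identity's synthetic exam date; the full unusual-attribute catalogue
#' (mixed clinical/PHI payloads, standard and private) at the patient's first
#' study and first series; one multi-line pixel burn-in on the first image of
#' each patient. Every injected PHI string is unique across the plan, so each
#' maps to exactly one answer-key entry.
#'
#' @param dataset The clean `dicom_dataset`.
#' @param seed Integer seed for the identity corpus.
#' @param records Optional pre-built list of `phi_record`s (one per patient,
#'   in dataset patient order); defaults to a generated corpus.
#' @param templates Template catalogue from [load_templates()].
#' @return An `injection_plan`: list with `directives` and `records`.
#' @export
default_plan <- function(dataset, seed, records = NULL,
                         templates = load_templates()) {
  meta <- dataset$meta
  patient_ids <- unique(meta$patient_id)
  studies_by_patient <- lapply(patient_ids, function(p) {
    unique(meta$study_uid[meta$patient_id == p])
  })
  if (is.null(records)) {
    records <- make_phi_corpus(seed, lengths(studies_by_patient))
  }
  if (length(records) != length(patient_ids)) {
    fail_with("need one phi_record per patient (%d patients, %d records)",
              length(patient_ids), length(records))
  }
  tpl <- function(id) templates[[id]] %||% fail_with("template %s missing", id)
  dirs <- list()
  add <- function(d) dirs[[length(dirs) + 1L]] <<- d
  set_from_template <- function(scope, selector, template_id, rec, study_index,
                                op = "set_tag") {
    t <- tpl(template_id)
    pay <- render_payload(t, rec, study_index)
    add(injection_directive(scope, selector, op, t$target,
                            list(value = pay$value, phi_spans = pay$phi_spans,
                                 retained_spans = pay$retained_spans)))
  }
  per_study_templates <- c("accession", "referring", "performing")
  first_study_templates <- c(
    "institution", "patient_comments", "patient_history", "study_comments",
    "reason_for_study", "requested_procedure", "station_name", "device_serial",
    "acq_device_code", "contrast_agent", "scheduled_start", "admitting_diag",
    "dataset_subtype", "issuer_of_pid", "receive_coil", "detector_desc",
    "derivation_desc", "requested_contrast", "structure_set_desc",
    "structure_set_date")
  first_series_templates <- c(
    "priv_imaging_options", "priv_source_ae", "priv_contrast_record",
    "priv_batch_desc", "priv_mao_buffer", "priv_kanji_dept", "priv_service_id",
    "priv_coil_id", "priv_phoenix", "priv_start_time")
  for (k in seq_along(patient_ids)) {
    pid <- patient_ids[k]
    rec <- records[[k]]
    # patient_id last: overwriting the Patient ID renames the scope selector
    # for any later Patient-scope directive
    for (id in c("patient_name", "birth_date", "patient_id")) {
      set_from_template("Patient", pid, id, rec, 1L)
    }
    studies <- studies_by_patient[[k]]
    for (j in seq_along(studies)) {
      su <- studies[j]
      for (id in per_study_templates) {
        set_from_template("Study", su, id, rec, j)
      }
      # move the placeholder study date onto the identity's synthetic exam
      # date; the resulting date is the PHI the answer key tracks
      clean_date <- get_value(
        dataset$instances[[meta$instance_uid[meta$study_uid == su][1]]],
        tag_path(0x0008, 0x0020))
      days <- as.integer(as.Date(rec$study_dates[min(j, length(rec$study_dates))],
                                 "%Y%m%d") -
                           as.Date(clean_date, "%Y%m%d"))
      add(injection_directive("Study", su, "shift_date", "(0008,0020)",
                              list(days = days)))
      if (j == 1L) {
        set_from_template("Study", su, "study_description", rec, 1L,
                          op = "substitute")
        for (id in first_study_templates) {
          set_from_template("Study", su, id, rec, 1L)
        }
        first_series <- meta$series_uid[meta$study_uid == su][1]
        for (id in first_series_templates) {
          set_from_template("Series", first_series, id, rec, 1L)
        }
        add(injection_directive(
          "Series", first_series, "string_replace", "(0008,103E)",
          list(old = "PHANTOM", new = paste(rec$aux[["series_token"]], "PHANTOM"),
               phi_spans = rec$aux[["series_token"]],
               retained_spans = "PHANTOM SERIES")))
        first_inst <- meta$instance_uid[meta$series_uid == first_series][1]
        add(injection_directive(
          "Instance", first_inst, "annotate_img", NULL,
          list(text = paste0("ID\n", rec$patient_id),
               rect = c(8L, 4L, 24L, 64L))))
      }
    }
  }
  structure(list(directives = dirs, records = records),
            class = "injection_plan")
}

#' @export
print.injection_plan <- function(x, ...) {
  cat(sprintf("<injection_plan: %d directives, %d identities>\n",
              length(x$directives), length(x$records)))
  invisible(x)
}

# --- plan / provenance file formats (JSON lines) --------------------------

#' Read / write injection plans and provenance logs
#'
#' Plans and provenance logs are JSON-lines files: one directive (or applied
#' operation) per line.
#'
#' @param plan An `injection_plan` or list of directives.
#' @param path File path.
#' @return `read_plan` returns a list of [injection_directive]s;
#'   `read_provenance` a list of `applied_operation`s.
#' @export
write_plan <- function(plan, path) {
  directives <- if (inherits(plan, "injection_plan")) plan$directives else plan
  lines <- vapply(directives, function(d) {
    jsonlite::toJSON(list(scope = d$scope, selector = d$selector, op = d$op,
                          tag = d$tag, params = d$params),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    params <- as.list(x$params)
    if (!is.null(params$rect)) params$rect <- as.integer(params$rect)
    injection_directive(x$scope, x$selector, x$op, x$tag, params)
  })
}

#' @rdname write_plan
#' @param provenance List of `applied_operation` records.
#' @export
write_provenance <- function(provenance, path) {
  lines <- vapply(provenance, function(op) {
    jsonlite::toJSON(
      list(scope = op$directive$scope, selector = op$directive$selector,
           final_selector = op$final_selector, op = op$directive$op,
           tag = op$directive$tag, params = op$directive$params,
           affected_instances = op$affected_instances,
           before_value = op$before_value, after_value = op$after_value,
           phi_spans = op$phi_spans, retained_spans = op$retained_spans,
           skipped_instances = op$skipped_instances,
           n_replacements = op$n_replacements),
      auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_provenance <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    params <- as.list(x$params)
    if (!is.null(params$rect)) params$rect <- as.integer(params$rect)
    d <- injection_directive(x$scope, x$selector, x$op, x$tag, params)
    op <- new_applied_op(d, as.character(x$affected_instances),
                         x$before_value, x$after_value,
                         as.character(x$phi_spans %||% character(0)),
                         as.character(x$retained_spans %||% character(0)),
                         as.character(x$skipped_instances %||% character(0)),
                         x$n_replacements %||% NA_integer_)
    op$final_selector <- x$final_selector
    op
  })
}
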