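# Answer-key model: distills the injector's provenance log (plus the dataset
# hierarchy) into the per-check ground truth used to score de-identification
# runs, and reads/writes keys and ID crosswalks.

ACTION_KINDS <- c("tag_retained", "text_notnull", "text_retained",
                  "text_removed", "date_shifted", "uid_changed",
                  "pixels_hidden")
KEY_SCOPES <- c("Patient", "Study", "Series", "Instance")

#' Answer-key entries
#'
#' One entry is one check: within a scope (identified by an
#' original-evaluation-dataset patient ID or UID), a tag must satisfy an
#' action. `action_text` carries the texts the action refers to: the spans
#' that must vanish (`text_removed`) or survive (`text_retained`), the
#' original date (`date_shifted`), the original UID (`uid_changed`), or the
#' burn-in rectangle `"r0,c0,r1,c1"` followed by the burned text
#' (`pixels_hidden`).
#'
#' @param scope One of Patient, Study, Series, Instance.
#' @param scope_selector Original-dataset identifier of the scoped node.
#' @param tag Tag-notation string (`NA` for `pixels_hidden`).
#' @param tag_name Human-readable attribute name.
#' @param action One of the seven action kinds.
#' @param action_text Character vector (see above).
#' @return An `answer_key_entry`.
#' @export
answer_key_entry <- function(scope, scope_selector, tag, tag_name, action,
                             action_text = character(0)) {
  scope <- match.arg(scope, KEY_SCOPES)
  action <- match.arg(action, ACTION_KINDS)
  if (action %in% c("text_removed", "text_retained") && !length(action_text)) {
    fail_with("%s entries need at least one action_text item", action)
  }
  if (action == "pixels_hidden") {
    if (!length(action_text) ||
        !grepl("^[0-9]+,[0-9]+,[0-9]+,[0-9]+$", action_text[1])) {
      fail_with("pixels_hidden entries need a leading rect item 'r0,c0,r1,c1'")
    }
    r <- as.integer(strsplit(action_text[1], ",")[[1]])
    if (!(r[1] < r[3] && r[2] < r[4])) fail_with("pixels_hidden rect is degenerate")
  }
  structure(list(scope = scope, scope_selector = as.character(scope_selector),
                 tag = if (is.null(tag)) NA_character_ else tag,
                 tag_name = tag_name, action = action,
                 action_text = as.character(action_text)),
            class = "answer_key_entry")
}

entry_tag_name <- function(tag) {
  if (is.null(tag)) return("Pixel Data")
  tp <- parse_tag(tag)
  if (is_private_tag(tp)) {
    priv <- load_private_dictionary()
    norm <- vapply(priv$tag, function(t) format_tag(parse_tag(t)), character(1))
    i <- match(format_tag(tp), norm)
    if (!is.na(i)) return(priv$description[i])
  }
  tag_display_name(tp)
}

#' Derive the answer key from provenance
#'
#' Maps every applied operation to its checks: text edits with PHI spans
#' yield one `text_removed` entry per span and one `text_retained` entry per
#' retained span; `shift_date` yields `date_shifted` (action text = the date
#' in the evaluation dataset); `annotate_img` yields `pixels_hidden`. When
#' the injected dataset is supplied, hierarchy checks are added:
#' `uid_changed` for every study, series and instance UID, and
#' `tag_retained` (plus `text_notnull` for Type 1) for every research-
#' critical profile attribute of each series' modality.
#'
#' @param provenance List of `applied_operation`s from [run_plan()].
#' @param dataset The injected `dicom_dataset` (optional; enables the
#'   hierarchy and retention checks).
#' @param profiles Profile table.
#' @return List of [answer_key_entry]s.
#' @export
derive_answer_key <- function(provenance, dataset = NULL,
                              profiles = default_profiles()) {
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e
  for (op in provenance) {
    d <- op$directive
    scope <- if (d$scope == "Collection") "Patient" else d$scope
    sel <- op$final_selector
    if (!length(op$affected_instances) && d$op != "annotate_img") next
    if (d$op %in% c("set_tag", "substitute", "string_replace")) {
      for (s in op$phi_spans) {
        add(answer_key_entry(scope, sel, d$tag, entry_tag_name(d$tag),
                             "text_removed", s))
      }
      for (s in op$retained_spans) {
        add(answer_key_entry(scope, sel, d$tag, entry_tag_name(d$tag),
                             "text_retained", s))
      }
    } else if (d$op == "shift_date") {
      add(answer_key_entry(scope, sel, d$tag, entry_tag_name(d$tag),
                           "date_shifted", op$after_value))
    } else if (d$op == "annotate_img") {
      if (length(op$phi_spans)) {
        add(answer_key_entry("Instance", op$affected_instances[1], NULL,
                             "Pixel Data", "pixels_hidden",
                             c(paste(d$params$rect, collapse = ","),
                               d$params$text)))
      }
    } else if (d$op == "delete_tag") {
      if (!is.null(op$before_value) && is.character(op$before_value) &&
          nzchar(op$before_value)) {
        add(answer_key_entry(scope, sel, d$tag, entry_tag_name(d$tag),
                             "text_removed", op$before_value))
      }
    }
  }
  if (!is.null(dataset)) {
    meta <- dataset$meta
    for (su in unique(meta$study_uid)) {
      add(answer_key_entry("Study", su, "(0020,000d)", "Study Instance UID",
                           "uid_changed", su))
    }
    for (se in unique(meta$series_uid)) {
      add(answer_key_entry("Series", se, "(0020,000e)", "Series Instance UID",
                           "uid_changed", se))
    }
    for (iu in meta$instance_uid) {
      add(answer_key_entry("Instance", iu, "(0008,0018)", "SOP Instance UID",
                           "uid_changed", iu))
    }
    # research-critical retention checks, per series (one modality each)
    ser <- unique(meta[c("series_uid", "modality")])
    for (i in seq_len(nrow(ser))) {
      rows <- profile_for_modality(ser$modality[i], profiles)
      for (j in seq_len(nrow(rows))) {
        if (!rows$type[j] %in% c("1", "2", "3")) next
        add(answer_key_entry("Series", ser$series_uid[i], rows$tag[j],
                             rows$name[j], "tag_retained"))
        if (rows$type[j] == "1") {
          add(answer_key_entry("Series", ser$series_uid[i], rows$tag[j],
                               rows$name[j], "text_notnull"))
        }
      }
    }
  }
  entries
}

# --- key file format ------------------------------------------------------

#' Read / write answer keys
#'
#' Keys are CSV files with columns `Scope`, `ScopeSelector`, `Tag`,
#' `TagName`, `Action`, `ActionText`; `ActionText` is a JSON-encoded list so
#' multi-item actions stay machine-parseable. Round-trips are lossless and
#' row-order stable.
#'
#' @param key List of [answer_key_entry]s.
#' @param path File path.
#' @return `read_key` returns the entry list.
#' @export
write_key <- function(key, path) {
  df <- data.frame(
    Scope = vapply(key, `[[`, character(1), "scope"),
    ScopeSelector = vapply(key, `[[`, character(1), "scope_selector"),
    Tag = vapply(key, `[[`, character(1), "tag"),
    TagName = vapply(key, `[[`, character(1), "tag_name"),
    Action = vapply(key, `[[`, character(1), "action"),
    ActionText = vapply(key, function(e) {
      as.character(jsonlite::toJSON(e$action_text))
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_key
#' @export
read_key <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("Scope", "ScopeSelector", "Tag", "TagName", "Action", "ActionText")
  if (!all(need %in% names(df))) fail_with("answer key lacks required columns")
  lapply(seq_len(nrow(df)), function(i) {
    if (!df$Action[i] %in% ACTION_KINDS) {
      fail_with("line %d: unknown answer-key action '%s'", i + 1L, df$Action[i])
    }
    answer_key_entry(df$Scope[i], df$ScopeSelector[i],
                     if (nzchar(df$Tag[i])) df$Tag[i] else NULL,
                     df$TagName[i], df$Action[i],
                     jsonlite::fromJSON(df$ActionText[i]))
  })
}

# --- crosswalks -----------------------------------------------------------

#' Read / write patient-ID and UID crosswalks
#'
#' A crosswalk is a two-column CSV (`old`, `new`) mapping original to
#' de-identified identifiers. Both columns must be injective; violations are
#' rejected on read and write. The optional date-shift table is a CSV with
#' columns `patient`, `days`.
#'
#' @param map Named character vector: `names(map)` are original IDs, values
#'   the de-identified IDs.
#' @param path File path.
#' @return `read_crosswalk` returns the named-vector map.
#' @export
write_crosswalk <- function(map, path) {
  check_injective(map)
  utils::write.csv(data.frame(old = names(map), new = unname(map),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("old", "new") %in% names(df))) {
    fail_with("crosswalk %s lacks old/new columns", path)
  }
  map <- stats::setNames(df$new, df$old)
  check_injective(map)
  map
}

check_injective <- function(map) {
  if (anyDuplicated(names(map))) {
    fail_with("crosswalk has duplicate source identifier: %s",
              names(map)[duplicated(names(map))][1])
  }
  if (anyDuplicated(unname(map))) {
    fail_with("crosswalk has duplicate target identifier: %s",
              unname(map)[duplicated(unname(map))][1])
  }
  invisible(TRUE)
}

#' @rdname write_crosswalk
#' @param shifts Data frame with columns `patient`, `days`.
#' @export
write_shift_table <- function(shifts, path) {
  utils::write.csv(shifts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_shift_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient", "days") %in% names(df))) {
    fail_with("shift table lacks patient/days columns")
  }
  df$patient <- as.character(df$patient)
  df
}
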