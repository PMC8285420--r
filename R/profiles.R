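# Modality attribute-type profiles: which attributes a conformant instance
# of each SOP class must carry (Type 1 with a value, Type 2 possibly empty),
# and how the phantom factory fills them. Shipped as a CSV transcribing the
# standard's general and modality-specific requirement rows plus the minimum
# structural attributes needed to form readable files.

MODALITIES <- c("CT", "MR", "PT", "DX", "CR", "MG")

SOP_CLASS_UIDS <- c(
  CT = "1.2.840.10008.5.1.4.1.1.2",
  MR = "1.2.840.10008.5.1.4.1.1.4",
  PT = "1.2.840.10008.5.1.4.1.1.128",
  DX = "1.2.840.10008.5.1.4.1.1.1.1",
  CR = "1.2.840.10008.5.1.4.1.1.1",
  MG = "1.2.840.10008.5.1.4.1.1.1.2",
  SC = "1.2.840.10008.5.1.4.1.1.7"
)

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "deidbench")
  if (path == "") {
    # during in-source development (pkgload) extdata sits under inst/
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) fail_with("bundled data file %s not found", file)
  path
}

#' Load the shipped modality profiles
#'
#' @param path Profile CSV (columns `tag`, `name`, `type`, `modality`,
#'   `rule`); defaults to the bundled table.
#' @return A data frame of profile rows.
#' @export
load_modality_profiles <- function(path = pkg_extdata("modality_profiles.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("tag", "name", "type", "modality", "rule")
  if (!all(need %in% names(df))) fail_with("profile file lacks required columns")
  bad <- setdiff(df$type, c("1", "1C", "2", "2C", "3"))
  if (length(bad)) fail_with("unknown attribute type in profile file: %s", bad[1])
  df
}

profiles_cache <- new.env(parent = emptyenv())

default_profiles <- function() {
  if (is.null(profiles_cache$df)) profiles_cache$df <- load_modality_profiles()
  profiles_cache$df
}

#' Load the private-attribute catalogue
#'
#' Each row names a manufacturer private attribute, its description and the
#' curation process-operation description (POD) applied to it: one of
#' `kept`, `hashed`, `offset`, `deleted`, `emptied`.
#'
#' @param path Catalogue CSV; defaults to the bundled table.
#' @return Data frame with columns `tag`, `description`, `pod`.
#' @export
load_private_dictionary <- function(path = pkg_extdata("private_dictionary.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  bad <- setdiff(df$pod, c("kept", "hashed", "offset", "deleted", "emptied"))
  if (length(bad)) fail_with("unknown POD value: %s", bad[1])
  # validate tag notation eagerly
  invisible(lapply(df$tag, parse_tag))
  df
}

# Profile rows applicable to one modality: modality-specific rows override
# "All" rows for the same tag.
profile_for_modality <- function(modality, profiles = default_profiles()) {
  all_rows <- profiles[profiles$modality == "All", , drop = FALSE]
  mod_rows <- profiles[profiles$modality == modality, , drop = FALSE]
  keep <- !(all_rows$tag %in% mod_rows$tag)
  out <- rbind(mod_rows, all_rows[keep, , drop = FALSE])
  out[order(out$tag), , drop = FALSE]
}

#' Attribute type of a tag for a modality
#'
#' Looks the tag up in the shipped profiles: a modality-specific row
#' overrides the row that applies to all modalities. Tags outside the
#' profiles yield the distinct value `"not_profiled"`.
#'
#' @param sop_class Modality code (`CT`, `MR`, `PT`, `DX`, `CR`, `MG`, `SC`).
#' @param tag A [tag_path] or tag-notation string.
#' @param profiles Profile table from [load_modality_profiles()].
#' @return One of `"T1"`, `"T1C"`, `"T2"`, `"T2C"`, `"T3"`, `"not_profiled"`.
#' @export
attribute_type <- function(sop_class, tag, profiles = default_profiles()) {
  if (is.character(tag)) tag <- parse_tag(tag)
  key <- format_tag(tag)
  norm <- vapply(profiles$tag, function(t) format_tag(parse_tag(t)), character(1))
  hit <- which(norm == key & profiles$modality == sop_class)
  if (!length(hit)) hit <- which(norm == key & profiles$modality == "All")
  if (!length(hit)) return("not_profiled")
  paste0("T", profiles$type[hit[1]])
}

#' Validate profile compliance of instances
#'
#' Checks that every Type 1 attribute of the instance's modality profile is
#' present with a non-empty value and every Type 2 attribute is present
#' (possibly empty). Conditional (1C/2C) and optional rows are not enforced.
#'
#' @param x A `dicom_instance` or `dicom_dataset`.
#' @param profiles Profile table.
#' @return A data frame of violations (zero rows when compliant), with
#'   columns `instance_uid`, `tag`, `name`, `type`, `problem`.
#' @export
validate_profile_compliance <- function(x, profiles = default_profiles()) {
  if (inherits(x, "dicom_dataset")) {
    out <- lapply(x$instances, validate_profile_compliance, profiles = profiles)
    out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    return(out)
  }
  inst <- x
  modality <- inst_modality(inst) %||% "?"
  rows <- profile_for_modality(modality, profiles)
  uid <- inst_uids(inst)[["instance"]]
  bad <- list()
  for (i in seq_len(nrow(rows))) {
    ty <- rows$type[i]
    if (!ty %in% c("1", "2")) next
    el <- get_element(inst, parse_tag(rows$tag[i]))
    if (is.null(el)) {
      bad[[length(bad) + 1L]] <- data.frame(
        instance_uid = uid, tag = rows$tag[i], name = rows$name[i],
        type = paste0("T", ty), problem = "absent", stringsAsFactors = FALSE)
    } else if (ty == "1" && value_is_empty(el$value)) {
      bad[[length(bad) + 1L]] <- data.frame(
        instance_uid = uid, tag = rows$tag[i], name = rows$name[i],
        type = "T1", problem = "empty", stringsAsFactors = FALSE)
    }
  }
  if (!length(bad)) {
    return(data.frame(instance_uid = character(0), tag = character(0),
                      name = character(0), type = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

value_is_empty <- function(value) {
  if (is.null(value)) return(TRUE)
  if (is.character(value)) return(length(value) == 0L || !nzchar(value[1]))
  length(value) == 0L
}
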