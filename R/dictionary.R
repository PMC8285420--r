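# Standard data dictionary for the attributes this toolkit manipulates,
# plus value-representation (VR) constraints for the supported VR subset.
# Anything outside this table is carried opaquely by the reader/writer.

dicom_dictionary <- local({
  rows <- list(
    # group, element, name, vr
    c("0008", "0008", "Image Type", "CS"),
    c("0008", "0016", "SOP Class UID", "UI"),
    c("0008", "0018", "SOP Instance UID", "UI"),
    c("0008", "0020", "Study Date", "DA"),
    c("0008", "0021", "Series Date", "DA"),
    c("0008", "0030", "Study Time", "TM"),
    c("0008", "0041", "Data Set Subtype", "LO"),
    c("0008", "0050", "Accession Number", "SH"),
    c("0008", "0060", "Modality", "CS"),
    c("0008", "0064", "Conversion Type", "CS"),
    c("0008", "0068", "Presentation Intent Type", "CS"),
    c("0008", "0070", "Manufacturer", "LO"),
    c("0008", "0080", "Institution Name", "LO"),
    c("0008", "0090", "Referring Physician's Name", "PN"),
    c("0008", "1010", "Station Name", "SH"),
    c("0008", "1030", "Study Description", "LO"),
    c("0008", "103E", "Series Description", "LO"),
    c("0008", "1050", "Performing Physician's Name", "PN"),
    c("0008", "1080", "Admitting Diagnoses Description", "LO"),
    c("0008", "2111", "Derivation Description", "ST"),
    c("0010", "0010", "Patient's Name", "PN"),
    c("0010", "0020", "Patient ID", "LO"),
    c("0010", "0021", "Issuer of Patient ID", "LO"),
    c("0010", "0030", "Patient's Birth Date", "DA"),
    c("0010", "0040", "Patient's Sex", "CS"),
    c("0010", "1040", "Patient's Address", "LO"),
    c("0010", "2154", "Patient's Telephone Numbers", "SH"),
    c("0010", "21B0", "Additional Patient History", "LT"),
    c("0010", "4000", "Patient Comments", "LT"),
    c("0018", "0010", "Contrast/Bolus Agent", "LO"),
    c("0018", "0015", "Body Part Examined", "CS"),
    c("0018", "0060", "KVP", "DS"),
    c("0018", "1000", "Device Serial Number", "LO"),
    c("0018", "1250", "Receive Coil Name", "SH"),
    c("0018", "1401", "Acquisition Device Processing Code", "LO"),
    c("0018", "1508", "Positioner Type", "CS"),
    c("0018", "7006", "Detector Description", "LT"),
    c("0020", "000D", "Study Instance UID", "UI"),
    c("0020", "000E", "Series Instance UID", "UI"),
    c("0020", "0010", "Study ID", "SH"),
    c("0020", "0011", "Series Number", "IS"),
    c("0020", "0013", "Instance Number", "IS"),
    c("0020", "0032", "Image Position (Patient)", "DS"),
    c("0020", "0037", "Image Orientation (Patient)", "DS"),
    c("0020", "0060", "Laterality", "CS"),
    c("0028", "0002", "Samples per Pixel", "US"),
    c("0028", "0004", "Photometric Interpretation", "CS"),
    c("0028", "0010", "Rows", "US"),
    c("0028", "0011", "Columns", "US"),
    c("0028", "0100", "Bits Allocated", "US"),
    c("0028", "0101", "Bits Stored", "US"),
    c("0028", "0102", "High Bit", "US"),
    c("0028", "0103", "Pixel Representation", "US"),
    c("0028", "0120", "Pixel Padding Value", "US"),
    c("0032", "1000", "Scheduled Study Start Date", "DA"),
    c("0032", "1030", "Reason for Study", "LO"),
    c("0032", "1060", "Requested Procedure Description", "LO"),
    c("0032", "1070", "Requested Contrast Agent", "LO"),
    c("0032", "4000", "Study Comments", "LT"),
    c("0040", "0318", "Organ Exposed", "CS"),
    c("3006", "0006", "Structure Set Description", "ST"),
    c("3006", "0008", "Structure Set Date", "DA"),
    c("7FE0", "0010", "Pixel Data", "OW")
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("group", "element", "name", "vr")
  df$key <- toupper(paste0(df$group, df$element))
  df
})

# Text VRs the toolkit decodes to character; everything else is binary/opaque.
TEXT_VRS <- c("PN", "LO", "SH", "ST", "LT", "DA", "TM", "UI", "CS", "IS", "DS",
              "AE", "AS")
SUPPORTED_VRS <- c(TEXT_VRS, "US", "UL", "OB", "OW", "SQ")
# Explicit VR encoding: these VRs use a 2-byte length field; everything else
# (OB, OW, OF, SQ, UT, UN, ...) has a 2-byte reserved field + 4-byte length.
SHORT_FORM_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FD", "FL",
                    "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                    "UI", "UL", "US")

is_text_vr <- function(vr) vr %in% TEXT_VRS

#' Look up an attribute in the built-in standard dictionary
#'
#' @param tag A standard [tag_path] (or resolved group/element pair).
#' @return A list with `name` and `vr`, or `NULL` if the tag is not in the
#'   dictionary.
#' @export
dict_lookup <- function(tag) {
  stopifnot(is_tag_path(tag), is.null(tag$creator))
  i <- match(tag_key(tag$group, tag$element), dicom_dictionary$key)
  if (is.na(i)) return(NULL)
  list(name = dicom_dictionary$name[i], vr = dicom_dictionary$vr[i])
}

# VR for a tag, defaulting private/unknown attributes to LO (long string).
default_vr <- function(tag) {
  if (is_private_tag(tag)) return("LO")
  hit <- dict_lookup(tag)
  if (is.null(hit)) "LO" else hit$vr
}

# Human-readable attribute name; private tags use their catalogue description
# when available, else the notation itself.
tag_display_name <- function(tag) {
  if (!is_private_tag(tag)) {
    hit <- dict_lookup(tag)
    if (!is.null(hit)) return(hit$name)
  }
  format_tag(tag)
}

date_is_valid <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^[0-9]{8}$", x) &&
    !is.na(as.Date(x, format = "%Y%m%d")) &&
    format(as.Date(x, format = "%Y%m%d"), "%Y%m%d") == x
}

uid_is_valid <- function(x) {
  is.character(x) && length(x) == 1L && nchar(x) >= 1L && nchar(x) <= 64L &&
    grepl("^[0-9.]+$", x)
}

# Validate a decoded value against its VR. Empty values are always legal
# (Type-2 semantics live in the profiles, not here).
validate_vr_value <- function(vr, value) {
  if (vr %in% c("US", "UL")) {
    if (!is.numeric(value) || any(is.na(value)) || any(value < 0)) {
      fail_with("%s value must be non-negative integers", vr)
    }
    lim <- if (vr == "US") 65535 else 4294967295
    if (any(value > lim)) fail_with("%s value exceeds %d", vr, lim)
    return(invisible(TRUE))
  }
  if (vr %in% c("OB", "OW")) {
    if (!(is.raw(value) || is.matrix(value) || is.numeric(value))) {
      fail_with("%s value must be raw bytes or a pixel matrix", vr)
    }
    return(invisible(TRUE))
  }
  if (vr == "SQ") {
    if (!(is.raw(value) && length(value) == 0L) && !is.raw(value)) {
      fail_with("SQ values are only carried as opaque bytes")
    }
    return(invisible(TRUE))
  }
  if (!is.character(value) || length(value) != 1L || is.na(value)) {
    fail_with("%s value must be a single string", vr)
  }
  if (value == "") return(invisible(TRUE))
  parts <- strsplit(value, "\\", fixed = TRUE)[[1]]
  maxlen <- switch(vr, LO = 64L, SH = 16L, ST = 1024L, LT = 10240L, PN = 324L,
                   CS = 16L, DA = 8L, TM = 16L, UI = 64L, IS = 12L, DS = 16L,
                   AE = 16L, AS = 4L, 10240L)
  if (any(nchar(parts) > maxlen)) {
    fail_with("%s value component exceeds %d characters", vr, maxlen)
  }
  if (vr == "DA") {
    for (p in parts) {
      if (!date_is_valid(p)) fail_with("invalid DA date value: %s", p)
    }
  }
  if (vr == "UI" && !all(vapply(parts, uid_is_valid, logical(1)))) {
    fail_with("invalid UI value: %s", value)
  }
  if (vr == "CS" && !all(grepl("^[A-Z0-9 _]*$", parts))) {
    fail_with("invalid CS value: %s", value)
  }
  if (vr %in% c("IS", "DS") &&
      !all(grepl("^[ +-]?[0-9.eE+-]+ ?$", parts))) {
    fail_with("invalid %s numeric string: %s", vr, value)
  }
  if (any(grepl("[^\\x20-\\x7E]", parts, perl = TRUE))) {
    fail_with("non-ASCII characters are not supported in %s values", vr)
  }
  invisible(TRUE)
}

# Number of backslash-separated components in a text value.
value_multiplicity <- function(vr, value) {
  if (!is_text_vr(vr) || !is.character(value) || value == "") return(length(value))
  length(strsplit(value, "\\", fixed = TRUE)[[1]])
}
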