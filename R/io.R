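# DICOM Part-10 serialization: 128-byte preamble + "DICM", Explicit VR
# Little Endian, single frame, uncompressed. The supported VR subset is
# decoded to R values; every other element is carried as opaque bytes and
# re-serialized byte-identically.

TRANSFER_SYNTAX_UID <- "1.2.840.10008.1.2.1"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.10.1188.1"

enc_u16 <- function(x) {
  x <- as.integer(x)
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

enc_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dec_u16 <- function(bytes, n = length(bytes) / 2L) {
  readBin(bytes, "integer", n = n, size = 2L, signed = FALSE,
          endian = "little")
}

dec_u32 <- function(bytes) {
  v <- readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
               endian = "little")
  ifelse(v < 0, v + 4294967296, v)
}

encode_value <- function(vr, value) {
  if (is.raw(value)) {
    bytes <- value
    pad <- as.raw(0L)
  } else if (vr == "US") {
    bytes <- enc_u16(value)
    pad <- as.raw(0L)
  } else if (vr == "UL") {
    bytes <- enc_u32(value)
    pad <- as.raw(0L)
  } else if (vr == "OW" && is.matrix(value)) {
    bytes <- enc_u16(as.vector(t(value)))  # row-major pixel order
    pad <- as.raw(0L)
  } else if (is_text_vr(vr)) {
    bytes <- charToRaw(as.character(value))
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  } else {
    fail_with("cannot encode VR %s from a %s value", vr, class(value)[1])
  }
  if (length(bytes) %% 2L == 1L) bytes <- c(bytes, pad)
  bytes
}

encode_element <- function(group, element, vr, value) {
  body <- encode_value(vr, value)
  vr2 <- substr(paste0(vr, "  "), 1L, 2L)
  if (!vr2 %in% SHORT_FORM_VRS) {
    header <- c(enc_u16(c(group, element)), charToRaw(vr2), as.raw(c(0L, 0L)),
                enc_u32(length(body)))
  } else {
    if (length(body) > 65534L) fail_with("value too long for short-form VR %s", vr)
    header <- c(enc_u16(c(group, element)), charToRaw(vr2), enc_u16(length(body)))
  }
  c(header, body)
}

build_file_meta <- function(inst) {
  sop_class <- get_value(inst, tag_path(0x0008, 0x0016)) %||% ""
  sop_inst <- get_value(inst, tag_path(0x0008, 0x0018)) %||% ""
  body <- c(
    encode_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    encode_element(0x0002, 0x0002, "UI", sop_class),
    encode_element(0x0002, 0x0003, "UI", sop_inst),
    encode_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_UID),
    encode_element(0x0002, 0x0012, "UI", IMPLEMENTATION_UID)
  )
  c(encode_element(0x0002, 0x0000, "UL", length(body)), body)
}

#' Serialize an instance to a Part-10 byte stream
#'
#' Emits the 128-byte preamble, the `DICM` magic, a minimal file-meta group
#' and every data element in ascending tag order, Explicit VR Little Endian.
#' Serialization is deterministic: equal instances give identical bytes.
#'
#' @param inst A `dicom_instance`.
#' @return A raw vector.
#' @export
write_instance <- function(inst) {
  stopifnot(inherits(inst, "dicom_instance"))
  check_instance(inst)
  inst <- sort_elements(inst)
  chunks <- vector("list", length(inst$elements) + 2L)
  chunks[[1]] <- c(raw(128L), charToRaw("DICM"))
  chunks[[2]] <- build_file_meta(inst)
  for (i in seq_along(inst$elements)) {
    el <- inst$elements[[i]]
    if (el$group == 0x0002L) next
    if (el$vr %in% SUPPORTED_VRS && !is.raw(el$value)) {
      validate_vr_value(el$vr, el$value)
    }
    chunks[[i + 2L]] <- encode_element(el$group, el$element, el$vr, el$value)
  }
  do.call(c, chunks[!vapply(chunks, is.null, logical(1))])
}

decode_text <- function(bytes) {
  # strip trailing padding (space or NUL) before conversion
  n <- length(bytes)
  while (n > 0L && bytes[n] %in% as.raw(c(0x00, 0x20))) n <- n - 1L
  if (n == 0L) return("")
  rawToChar(bytes[seq_len(n)])
}

#' Parse a Part-10 byte stream
#'
#' Inverse of [write_instance()]. Requires the `DICM` magic at offset 128 and
#' the Explicit VR Little Endian transfer syntax; compressed or implicit-VR
#' streams are rejected with an unsupported-format error. Elements with
#' unsupported VRs are preserved as opaque bytes.
#'
#' @param bytes A raw vector holding one Part-10 file.
#' @return A `dicom_instance`.
#' @export
read_instance <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) < 140L ||
      !identical(rawToChar(bytes[129:132]), "DICM")) {
    fail_with("not a DICOM Part-10 stream: missing DICM magic at offset 128")
  }
  pos <- 133L
  n <- length(bytes)
  elements <- list()
  transfer_syntax <- NULL
  rows <- NULL
  cols <- NULL
  while (pos + 7L <= n) {
    group <- dec_u16(bytes[pos:(pos + 1L)], 1L)
    element <- dec_u16(bytes[(pos + 2L):(pos + 3L)], 1L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!vr %in% SHORT_FORM_VRS) {
      len <- dec_u32(bytes[(pos + 8L):(pos + 11L)])
      pos <- pos + 12L
    } else {
      len <- dec_u16(bytes[(pos + 6L):(pos + 7L)], 1L)
      pos <- pos + 8L
    }
    if (pos + len - 1L > n) fail_with("truncated element (%04x,%04x)", group, element)
    body <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0L)
    pos <- pos + as.integer(len)
    vr <- trimws(vr)
    if (group == 0x0002L) {
      if (element == 0x0010L) transfer_syntax <- decode_text(body)
      next
    }
    value <- if (vr %in% TEXT_VRS) {
      decode_text(body)
    } else if (vr == "US") {
      dec_u16(body)
    } else if (vr == "UL") {
      as.integer(dec_u32(body))
    } else if (vr == "OW" && group == 0x7FE0L && element == 0x0010L &&
               !is.null(rows) && !is.null(cols) &&
               length(body) == 2L * rows * cols) {
      matrix(dec_u16(body), nrow = rows, ncol = cols, byrow = TRUE)
    } else {
      body
    }
    if (group == 0x0028L && element == 0x0010L) rows <- value[1]
    if (group == 0x0028L && element == 0x0011L) cols <- value[1]
    elements[[tag_key(group, element)]] <-
      list(group = group, element = element, vr = vr, value = value)
  }
  if (is.null(transfer_syntax)) {
    fail_with("stream has no transfer syntax element (0002,0010)")
  }
  if (!identical(transfer_syntax, TRANSFER_SYNTAX_UID)) {
    fail_with("unsupported transfer syntax %s: only Explicit VR Little Endian is supported",
              transfer_syntax)
  }
  new_instance(elements)
}

#' @rdname write_instance
#' @param path File path to write to / read from.
#' @export
write_dicom_file <- function(inst, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeBin(write_instance(inst), path)
  invisible(path)
}

#' @rdname read_instance
#' @param path File path to read.
#' @export
read_dicom_file <- function(path) {
  read_instance(readBin(path, "raw", n = file.size(path)))
}

# --- dataset container ----------------------------------------------------

#' DICOM dataset container
#'
#' A `dicom_dataset` is a named list of instances (keyed by SOP Instance UID)
#' plus a metadata table with one row per instance (patient ID, study /
#' series / instance UIDs, modality). The metadata is always derivable from
#' the instances; [dataset_meta()] recomputes it.
#'
#' @param instances List of `dicom_instance` objects.
#' @return A `dicom_dataset`.
#' @export
new_dataset <- function(instances) {
  uids <- vapply(instances, function(x) inst_uids(x)[["instance"]], character(1))
  if (anyDuplicated(uids)) fail_with("duplicate SOP Instance UIDs in dataset")
  names(instances) <- uids
  ds <- structure(list(instances = instances, meta = NULL),
                  class = "dicom_dataset")
  ds$meta <- dataset_meta(ds)
  ds
}

#' @rdname new_dataset
#' @param dataset A `dicom_dataset`.
#' @export
dataset_meta <- function(dataset) {
  grab <- function(key) {
    vapply(dataset$instances, function(inst) {
      v <- inst$elements[[key]]$value
      if (is.null(v)) NA_character_ else v
    }, character(1), USE.NAMES = FALSE)
  }
  data.frame(instance_uid = grab("00080018"), series_uid = grab("0020000E"),
             study_uid = grab("0020000D"), patient_id = grab("00100020"),
             modality = grab("00080060"), stringsAsFactors = FALSE)
}

# Refresh the metadata table after instances were modified in place.
refresh_meta <- function(dataset) {
  dataset$meta <- dataset_meta(dataset)
  dataset
}

#' @export
print.dicom_dataset <- function(x, ...) {
  cat(sprintf("<dicom_dataset: %d instances, %d patients, %d studies, %d series>\n",
              nrow(x$meta), length(unique(x$meta$patient_id)),
              length(unique(x$meta$study_uid)),
              length(unique(x$meta$series_uid))))
  invisible(x)
}

sanitize_path_part <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Read / write a dataset directory
#'
#' Files are laid out `<dir>/<modality>/<patient>/<study>/<series>/<n>.dcm`.
#' `read_dataset` accepts any directory tree containing `.dcm` files.
#'
#' @param dataset A `dicom_dataset`.
#' @param dir Directory root.
#' @return `write_dataset` returns the directory invisibly; `read_dataset`
#'   returns a `dicom_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  meta <- dataset$meta
  ord <- order(meta$modality, meta$patient_id, meta$study_uid, meta$series_uid,
               meta$instance_uid)
  counter <- 0L
  last_series <- ""
  for (i in ord) {
    if (!identical(meta$series_uid[i], last_series)) {
      counter <- 0L
      last_series <- meta$series_uid[i]
    }
    counter <- counter + 1L
    path <- file.path(
      dir,
      sanitize_path_part(meta$modality[i]),
      sanitize_path_part(meta$patient_id[i]),
      sanitize_path_part(meta$study_uid[i]),
      sanitize_path_part(meta$series_uid[i]),
      sprintf("%05d.dcm", counter)
    )
    write_dicom_file(dataset$instances[[meta$instance_uid[i]]], path)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", recursive = TRUE,
                           full.names = TRUE))
  if (!length(files)) fail_with("no .dcm files under %s", dir)
  new_dataset(lapply(files, read_dicom_file))
}
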