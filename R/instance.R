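#' In-memory DICOM instances
#'
#' A `dicom_instance` holds an ordered collection of data elements plus the
#' decoded pixel matrix. Elements are stored in ascending tag order under
#' canonical `"GGGGEEEE"` keys; each element is a list with `group`,
#' `element`, `vr` and `value`. Text VRs hold a single string
#' (backslash-separated for multi-valued attributes), `US`/`UL` hold integer
#' vectors, Pixel Data holds a 16-bit integer matrix, and unsupported VRs are
#' carried as opaque raw payloads so they re-serialize byte-identically.
#'
#' @param elements Named list of elements (may be empty).
#' @return A `dicom_instance`.
#' @export
new_instance <- function(elements = list()) {
  inst <- structure(list(elements = elements), class = "dicom_instance")
  sort_elements(inst)
}

sort_elements <- function(inst) {
  if (length(inst$elements)) {
    inst$elements <- inst$elements[order(names(inst$elements), method = "radix")]
  }
  inst
}

#' @export
print.dicom_instance <- function(x, ...) {
  cat(sprintf("<dicom_instance: %d elements, modality %s>\n",
              length(x$elements),
              get_value(x, tag_path(0x0008, 0x0060)) %||% "?"))
  invisible(x)
}

# --- element access -------------------------------------------------------

# Resolve a tag_path to a concrete "GGGGEEEE" key within an instance.
# Private creator-form tags are resolved through the creator-reservation
# elements (gggg,0010)..(gggg,00FF); NULL when the creator is not reserved.
resolve_key <- function(inst, tag) {
  if (is.null(tag$creator)) {
    return(tag_key(tag$group, tag$element))
  }
  blk <- creator_block(inst, tag$group, tag$creator)
  if (is.null(blk)) return(NULL)
  tag_key(tag$group, blk * 256L + tag$private_byte)
}

# The reserved block byte (0x10..0xFF) for a creator label, or NULL.
creator_block <- function(inst, group, creator) {
  keys <- names(inst$elements)
  if (!length(keys)) return(NULL)
  prefix <- sprintf("%04X00", group)
  cand <- which(startsWith(keys, prefix))
  for (i in cand) {
    el <- key_element(keys[i])
    if (el < 0x10L || el > 0xFFL) next
    v <- inst$elements[[i]]$value
    if (is.character(v) && (identical(v, creator) ||
                            identical(trimws(v), creator))) {
      return(el)
    }
  }
  NULL
}

#' Resolve a private attribute within an instance
#'
#' Locates the creator-reservation element whose value equals the tag's
#' creator label and returns the element at the reserved block plus the
#' tag's byte offset. Absence (unreserved creator or missing element) is a
#' valid result, not an error.
#'
#' @param inst A `dicom_instance`.
#' @param tag A private [tag_path] in creator form.
#' @return The element list, or `NULL` when absent.
#' @export
resolve_private <- function(inst, tag) {
  stopifnot(is_tag_path(tag))
  if (!is_private_tag(tag) || is.null(tag$creator)) {
    fail_with("resolve_private requires a creator-form private tag")
  }
  key <- resolve_key(inst, tag)
  if (is.null(key)) return(NULL)
  inst$elements[[key]]
}

#' Get / set / delete data elements
#'
#' `get_element` returns the element (or `NULL`); `get_value` just its value.
#' `set_element` creates or overwrites an element, auto-reserving a private
#' creator block when needed; `delete_element` removes one (a no-op when
#' absent).
#'
#' @param inst A `dicom_instance`.
#' @param tag A [tag_path] (standard, or private in creator form).
#' @param vr Value representation; defaults to the dictionary VR.
#' @param value Element value, validated against `vr`.
#' @return `get_element`: an element list or `NULL`; the others return the
#'   modified instance.
#' @export
get_element <- function(inst, tag) {
  key <- resolve_key(inst, tag)
  if (is.null(key)) return(NULL)
  inst$elements[[key]]
}

#' @rdname get_element
#' @export
get_value <- function(inst, tag) {
  el <- get_element(inst, tag)
  if (is.null(el)) NULL else el$value
}

#' @rdname get_element
#' @export
set_element <- function(inst, tag, value, vr = NULL) {
  stopifnot(is_tag_path(tag))
  vr <- vr %||% default_vr(tag)
  if (!vr %in% SUPPORTED_VRS && !is.raw(value)) {
    fail_with("unsupported VR %s requires a raw payload", vr)
  }
  if (vr %in% SUPPORTED_VRS) validate_vr_value(vr, value)
  if (!is.null(tag$creator)) {
    blk <- creator_block(inst, tag$group, tag$creator)
    if (is.null(blk)) {
      blk <- reserve_creator(inst, tag$group, tag$creator)
      inst <- blk$inst
      blk <- blk$block
    }
    key <- tag_key(tag$group, blk * 256L + tag$private_byte)
    grp <- tag$group
    el <- blk * 256L + tag$private_byte
  } else {
    key <- tag_key(tag$group, tag$element)
    grp <- tag$group
    el <- tag$element
  }
  is_new <- is.null(inst$elements[[key]])
  inst$elements[[key]] <- list(group = grp, element = el, vr = vr, value = value)
  if (is_new) inst <- sort_elements(inst)  # overwrites keep their position
  inst
}

# Reserve the lowest free creator block in a group for a creator label.
reserve_creator <- function(inst, group, creator) {
  keys <- names(inst$elements)
  used <- integer(0)
  if (length(keys)) {
    grp <- key_group(keys)
    el <- key_element(keys)
    used <- el[grp == group & el >= 0x10L & el <= 0xFFL]
  }
  free <- setdiff(0x10:0xFF, used)
  if (!length(free)) fail_with("no free private block in group %04x", group)
  blk <- free[1]
  key <- tag_key(group, blk)
  inst$elements[[key]] <- list(group = group, element = blk, vr = "LO",
                               value = creator)
  list(inst = sort_elements(inst), block = as.integer(blk))
}

#' @rdname get_element
#' @export
delete_element <- function(inst, tag) {
  key <- resolve_key(inst, tag)
  if (!is.null(key) && key %in% names(inst$elements)) {
    inst$elements[[key]] <- NULL
  }
  inst
}

# --- common accessors -----------------------------------------------------

#' Instance accessors
#'
#' Convenience readers for the identifying attributes and the pixel matrix.
#'
#' @param inst A `dicom_instance`.
#' @return `inst_uids`: named character vector with `study`, `series`,
#'   `instance`; `inst_modality`: the modality code; `inst_pixels`: the
#'   integer pixel matrix (or `NULL`); `inst_patient_id`: Patient ID value.
#' @export
inst_uids <- function(inst) {
  c(study = get_value(inst, tag_path(0x0020, 0x000D)) %||% NA_character_,
    series = get_value(inst, tag_path(0x0020, 0x000E)) %||% NA_character_,
    instance = get_value(inst, tag_path(0x0008, 0x0018)) %||% NA_character_)
}

#' @rdname inst_uids
#' @export
inst_modality <- function(inst) get_value(inst, tag_path(0x0008, 0x0060))

#' @rdname inst_uids
#' @export
inst_patient_id <- function(inst) get_value(inst, tag_path(0x0010, 0x0020))

#' @rdname inst_uids
#' @export
inst_pixels <- function(inst) get_value(inst, tag_path(0x7FE0, 0x0010))

#' @rdname inst_uids
#' @param pixels Integer matrix of 16-bit pixel values; Rows/Columns are kept
#'   in sync.
#' @export
set_pixels <- function(inst, pixels) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L) || any(pixels > 65535L)) {
    fail_with("pixel values must fit unsigned 16-bit")
  }
  inst <- set_element(inst, tag_path(0x0028, 0x0010), nrow(pixels), "US")
  inst <- set_element(inst, tag_path(0x0028, 0x0011), ncol(pixels), "US")
  set_element(inst, tag_path(0x7FE0, 0x0010), pixels, "OW")
}

# Structural invariants: Rows/Columns agree with the pixel array and the UID
# triple is present. Called before serialization.
check_instance <- function(inst) {
  px <- inst_pixels(inst)
  if (!is.null(px)) {
    r <- get_value(inst, tag_path(0x0028, 0x0010))
    c <- get_value(inst, tag_path(0x0028, 0x0011))
    if (is.null(r) || is.null(c) || r != nrow(px) || c != ncol(px)) {
      fail_with("Rows/Columns disagree with the pixel array shape")
    }
  }
  invisible(TRUE)
}
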