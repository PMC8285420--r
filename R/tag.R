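#' DICOM tag addresses
#'
#' A `tag_path` addresses either a standard attribute, written
#' `"(gggg,eeee)"`, or a private attribute, written
#' `"(gggg,\"CREATOR\",xx)"` where `CREATOR` is the private-creator label and
#' `xx` the one-byte element offset inside the creator's reserved block.
#' Private attributes live in odd-numbered groups; standard attributes in
#' even-numbered groups.
#'
#' @param group,element Integer group/element numbers (0..0xFFFF).
#' @param creator Private-creator label, or `NULL` for standard tags.
#' @param private_byte One-byte element offset within the creator block
#'   (0..0xFF), required when `creator` is given.
#' @return A `tag_path` object.
#' @export
tag_path <- function(group, element = NULL, creator = NULL, private_byte = NULL) {
  group <- as.integer(group)
  if (is.na(group) || group < 0L || group > 0xFFFFL) {
    fail_with("tag group out of range")
  }
  if (!is.null(creator)) {
    if (group %% 2L == 0L) {
      fail_with("private-creator tag form requires an odd group: (%04x,...)", group)
    }
    private_byte <- as.integer(private_byte)
    if (is.na(private_byte) || private_byte < 0L || private_byte > 0xFFL) {
      fail_with("private element byte must lie in [0x00, 0xFF]")
    }
    out <- list(group = group, element = NULL, creator = as.character(creator),
                private_byte = private_byte)
  } else {
    element <- as.integer(element)
    if (is.na(element) || element < 0L || element > 0xFFFFL) {
      fail_with("tag element out of range")
    }
    out <- list(group = group, element = element, creator = NULL,
                private_byte = NULL)
  }
  structure(out, class = "tag_path")
}

#' @rdname tag_path
#' @param tag Object to test.
#' @export
is_tag_path <- function(tag) inherits(tag, "tag_path")

#' @rdname tag_path
#' @export
is_private_tag <- function(tag) {
  stopifnot(is_tag_path(tag))
  tag$group %% 2L == 1L
}

#' Parse DICOM tag notation
#'
#' Accepts `"(gggg,eeee)"` for standard tags and
#' `"(gggg,\"CREATOR\",xx)"` for private tags, the notation used throughout
#' attribute catalogues and answer keys.
#'
#' @param text A single tag-notation string.
#' @return A [tag_path].
#' @examples
#' parse_tag("(0010,0010)")
#' parse_tag('(0009,"GEMS_PETD_01",37)')
#' @export
parse_tag <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    fail_with("tag notation must be a single string")
  }
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^\\(([0-9a-fA-F]{4}),([0-9a-fA-F]{4})\\)$", txt))[[1]]
  if (length(m) == 3L) {
    return(tag_path(strtoi(m[2], 16L), strtoi(m[3], 16L)))
  }
  m <- regmatches(
    txt,
    regexec("^\\(([0-9a-fA-F]{4}),\"([^\"]+)\",([0-9a-fA-F]{1,2})\\)$", txt)
  )[[1]]
  if (length(m) == 4L) {
    grp <- strtoi(m[2], 16L)
    if (grp %% 2L == 0L) {
      fail_with("malformed tag %s: creator form on an even group", text)
    }
    return(tag_path(grp, creator = m[3], private_byte = strtoi(m[4], 16L)))
  }
  fail_with("malformed tag notation: %s", text)
}

#' Format a tag back to its notation
#'
#' Inverse of [parse_tag()]; `parse_tag(format_tag(x))` reproduces `x`.
#'
#' @param tag A [tag_path].
#' @return A tag-notation string.
#' @export
format_tag <- function(tag) {
  stopifnot(is_tag_path(tag))
  if (!is.null(tag$creator)) {
    sprintf("(%04x,\"%s\",%02x)", tag$group, tag$creator, tag$private_byte)
  } else {
    sprintf("(%04x,%04x)", tag$group, tag$element)
  }
}

#' @export
print.tag_path <- function(x, ...) {
  cat(format_tag(x), "\n")
  invisible(x)
}

#' @export
format.tag_path <- function(x, ...) format_tag(x)

# Canonical element key "GGGGEEEE" for resolved (group, element) addresses.
tag_key <- function(group, element) sprintf("%04X%04X", group, element)

key_group <- function(key) strtoi(substr(key, 1L, 4L), 16L)
key_element <- function(key) strtoi(substr(key, 5L, 8L), 16L)
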