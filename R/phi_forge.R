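# Seeded synthetic-PHI generation. Everything here is a pure function of
# (seed, indices): the same inputs always regenerate the identical identity,
# which is what makes the injected dataset and its answer key reproducible.

FAMILY_NAMES <- c(
  "ROGERS", "ROBERTSON", "PHILLIPS", "BAILEY", "SMITH", "JOHNSON", "WILLIAMS",
  "BROWN", "JONES", "GARCIA", "MILLER", "DAVIS", "WILSON", "ANDERSON",
  "THOMAS", "TAYLOR", "MOORE", "JACKSON", "MARTIN", "LEE", "THOMPSON",
  "WHITE", "HARRIS", "CLARK", "LEWIS", "WALKER", "HALL", "ALLEN", "YOUNG",
  "KING", "WRIGHT", "SCOTT", "GREEN", "BAKER", "ADAMS", "NELSON", "CARTER",
  "MITCHELL", "PEREZ", "TURNER")

GIVEN_NAMES <- c(
  "BILLY", "JESSE", "JOHN", "THERESA", "MARY", "JAMES", "ROBERT", "MICHAEL",
  "DAVID", "RICHARD", "JOSEPH", "CHARLES", "LINDA", "BARBARA", "ELIZABETH",
  "JENNIFER", "MARIA", "SUSAN", "MARGARET", "DOROTHY", "DANIEL", "PAUL",
  "MARK", "DONALD", "GEORGE", "KAREN", "NANCY", "BETTY", "HELEN", "SANDRA",
  "STEVEN", "EDWARD", "BRIAN", "RONALD", "ANTHONY", "KEVIN", "LAURA",
  "SARAH", "KIMBERLY", "DEBORAH")

INSTITUTION_PREFIX <- c(
  "Treetop", "Lakeside", "Riverview", "Summit", "Oakdale", "Maplewood",
  "Hillcrest", "Brookfield", "Stonebridge", "Clearwater", "Fairview",
  "Meadowbrook", "Pinehurst", "Silverlake", "Crestwood")

INSTITUTION_SUFFIX <- c(
  "Medical Center", "General Hospital", "Regional Hospital",
  "Community Hospital", "Imaging Center", "Memorial Hospital")

STREET_NAMES <- c(
  "Maple Street", "Oak Avenue", "Cedar Lane", "Elm Drive", "Pine Road",
  "Birch Court", "Walnut Boulevard", "Chestnut Way", "Spruce Terrace",
  "Willow Place")

CITY_NAMES <- c(
  "Springfield", "Riverton", "Fairmont", "Georgetown", "Clinton", "Salem",
  "Madison", "Ashland", "Bristol", "Dayton", "Franklin", "Greenville")

STATE_CODES <- c("AK", "AR", "AZ", "CO", "GA", "IA", "KS", "KY", "ME", "MO",
                 "NE", "NM", "OH", "OR", "TN", "VA", "VT", "WI")

pn_display <- function(pn) {
  comps <- strsplit(pn, "^", fixed = TRUE)[[1]]
  title <- function(x) {
    paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  }
  paste(rev(vapply(comps, title, character(1))), collapse = " ")
}

fmt_date <- function(d) format(d, "%Y%m%d")

#' Shift a DICOM date
#'
#' Offsets a calendar-valid `YYYYMMDD` date by a signed number of days.
#' `shift_date(shift_date(d, k), -k)` recovers `d`.
#'
#' @param date A `YYYYMMDD` string.
#' @param days Signed integer day offset.
#' @return The shifted `YYYYMMDD` string.
#' @examples
#' shift_date("19430722", -14)
#' shift_date("20160228", 2)  # crosses a leap day
#' @export
shift_date <- function(date, days) {
  if (!date_is_valid(date)) fail_with("invalid DA date value: %s", date)
  fmt_date(as.Date(date, format = "%Y%m%d") + as.integer(days))
}

# Injective 6-digit patient index permutation; the multiplier depends only on
# the seed so that one cohort shares one permutation.
perm6 <- function(seed, index) {
  a <- derive_seed(seed, 991) %% 499999L * 2L + 1L     # odd
  if (a %% 5L == 0L) a <- a + 2L
  b <- derive_seed(seed, 992) %% 1000000L
  as.integer((as.numeric(a) * index + b) %% 1000000L)
}

#' Generate a synthetic patient identity
#'
#' Builds one patient's complete synthetic-PHI record: person name
#' (caret-delimited, uppercase), a unique 10-digit patient ID, calendar-valid
#' birth and study dates (birth precedes the first study by 18-90 years),
#' date-prefixed accession numbers (`YYYYMMDD` + letter + 6 digits), US-style
#' address and phone, per-study physicians, an institution, and a pool of
#' auxiliary per-record tokens used by the payload templates. The record is a
#' pure function of `(seed, patient_index)`.
#'
#' @param seed Integer master seed.
#' @param patient_index Zero-based patient index within the cohort.
#' @param n_studies Number of studies the patient will receive.
#' @param salt Internal re-draw counter used by [make_phi_corpus()] to
#'   resolve rare cross-patient value collisions; leave at 0.
#' @return A `phi_record` list.
#' @export
make_phi_record <- function(seed, patient_index, n_studies = 1L, salt = 0L) {
  stopifnot(patient_index >= 0L, n_studies >= 1L)
  rs <- derive_seed(seed, patient_index, 7, salt * 1009)
  with_seed(rs, {
    family <- sample(FAMILY_NAMES, 1L)
    given <- sample(GIVEN_NAMES, 1L)
    patient_name <- paste(family, given, sep = "^")
    patient_id <- sprintf("%04d%06d", sample(0:9999, 1L),
                          perm6(seed, patient_index))
    first_study <- as.Date("2012-01-01") + sample(0:2921, 1L)  # 2012-2019
    study_dates <- fmt_date(first_study +
                              c(0L, cumsum(sample(30:400, max(0L, n_studies - 1L),
                                                  replace = TRUE))))
    birth_date <- fmt_date(first_study - sample(6574:32873, 1L))  # 18-90 yr
    # the 6-digit body is the injective per-patient permutation value, so
    # accessions never collide across patients; within a patient the study
    # date prefix (studies are >= 30 days apart) keeps them distinct
    acc_letters <- sample(LETTERS, n_studies, replace = TRUE)
    accession_numbers <- sprintf("%s%s%06d", study_dates, acc_letters,
                                 perm6(seed, patient_index))
    # physicians and operators never reuse the patient's family name, so no
    # two injected spans of one record can coincide
    other_families <- setdiff(FAMILY_NAMES, family)
    referring <- paste(sample(other_families, n_studies),
                       sample(GIVEN_NAMES, n_studies), sep = "^")
    performing <- paste(sample(setdiff(other_families, sub("\\^.*", "", referring)),
                               n_studies),
                        sample(GIVEN_NAMES, n_studies), sep = "^")
    institution <- paste(sample(INSTITUTION_PREFIX, 1L),
                         sample(INSTITUTION_SUFFIX, 1L))
    address <- sprintf("%d %s, %s, %s %05d",
                       sample(100:9999, 1L), sample(STREET_NAMES, 1L),
                       sample(CITY_NAMES, 1L), sample(STATE_CODES, 1L),
                       sample(10000:99999, 1L))
    phone <- sprintf("(%03d) 555-%04d", sample(200:989, 1L), sample(0:9999, 1L))
    sex <- sample(c("M", "F"), 1L)
    operator <- paste(sample(other_families, 1L), sample(GIVEN_NAMES, 1L),
                      sep = "^")
    aux <- c(
      name_caps = paste(given, family),
      name_comma = paste0(pn_display(paste(given, family, sep = "^")), ","),
      name_short = paste0(substr(given, 1, 1), ". ", pn_display(family)),
      institution_caps = toupper(institution),
      operator_name = operator,
      order_note = pn_display(referring[1]),
      serial_no = sprintf("SN%08d", sample(0:99999999, 1L)),
      department = sprintf("Department %04d", sample(0:9999, 1L)),
      coil_token = sprintf("COIL%06d", sample(0:999999, 1L)),
      batch_token = sprintf("B%08d", sample(0:99999999, 1L)),
      mao_token = sprintf("(%03d) 555-%04d", sample(200:989, 1L), sample(0:9999, 1L)),
      svc_token = sprintf("SVC%06d", sample(0:999999, 1L)),
      img_token = sprintf("IMG%06d", sample(0:999999, 1L)),
      ae_token = sprintf("AE%08d", sample(0:99999999, 1L)),
      detector_token = sprintf("DET%06d", sample(0:999999, 1L)),
      subtype_token = sprintf("SUB%06d", sample(0:999999, 1L)),
      station_token = sprintf("STN%05d", sample(0:99999, 1L)),
      admit_token = sprintf("ADM%06d", sample(0:999999, 1L)),
      deriv_token = sprintf("DRV%06d", sample(0:999999, 1L)),
      req_token = sprintf("RQ%06d", sample(0:999999, 1L)),
      struct_token = sprintf("RTS%06d", sample(0:999999, 1L)),
      imaging_token = sprintf("IO%06d", sample(0:999999, 1L)),
      toshiba_token = sprintf("TCB%06d", sample(0:999999, 1L)),
      kanji_token = sprintf("KDEPT%04d", sample(0:9999, 1L)),
      recv_token = sprintf("RC%06d", sample(0:999999, 1L)),
      phoenix_token = sprintf("PHX%06d", sample(0:999999, 1L)),
      start_token = sprintf("%06d.00", sample(0:999999, 1L)),
      series_token = sprintf("SER%06d", sample(0:999999, 1L)),
      sched_date = shift_date(study_dates[1], -3L),
      struct_date = shift_date(study_dates[1], 1L)
    )
    structure(
      list(patient_name = patient_name, patient_id = patient_id,
           birth_date = birth_date, sex = sex, address = address,
           phone = phone, accession_numbers = accession_numbers,
           referring_physician = referring, performing_physician = performing,
           institution = institution, study_dates = study_dates,
           comments_seed = "Patient tolerated the procedure well",
           aux = aux, patient_index = patient_index, seed = seed),
      class = "phi_record")
  })
}

#' @export
print.phi_record <- function(x, ...) {
  cat(sprintf("<phi_record %s (%s), id %s, %d studies>\n", x$patient_name,
              x$birth_date, x$patient_id, length(x$study_dates)))
  invisible(x)
}

#' The worked-example patient
#'
#' A fixed record reproducing the published answer-key example: patient
#' ROGERS^BILLY, ID 6774825273, born 19430722, imaged at Treetop Medical
#' Center with accession numbers 20130912E245583 and 20130912E801911 and
#' per-study physician pairs ROBERTSON^JESSE / PHILLIPS^JOHN and
#' BAILEY^THERESA / SMITH^MARY.
#'
#' @return A `phi_record` with two studies.
#' @export
phi_record_example <- function() {
  rec <- make_phi_record(1L, 0L, n_studies = 2L)
  rec$patient_name <- "ROGERS^BILLY"
  rec$patient_id <- "6774825273"
  rec$birth_date <- "19430722"
  rec$sex <- "M"
  rec$institution <- "Treetop Medical Center"
  rec$study_dates <- c("20130912", "20130912")
  rec$accession_numbers <- c("20130912E245583", "20130912E801911")
  rec$referring_physician <- c("ROBERTSON^JESSE", "BAILEY^THERESA")
  rec$performing_physician <- c("PHILLIPS^JOHN", "SMITH^MARY")
  rec$aux[["order_note"]] <- pn_display(rec$referring_physician[1])
  rec$aux[["name_caps"]] <- "BILLY ROGERS"
  rec$aux[["name_comma"]] <- "Billy Rogers,"
  rec$aux[["name_short"]] <- "B. Rogers"
  rec$aux[["institution_caps"]] <- toupper(rec$institution)
  rec$aux[["sched_date"]] <- shift_date("20130912", -3L)
  rec$aux[["struct_date"]] <- shift_date("20130912", 1L)
  rec
}

# The distinct identity-bearing strings of one record (name forms, IDs,
# dates, tokens). Used both for collision screening and as a leakage corpus.
record_span_values <- function(record) {
  unname(c(record$patient_name, pn_display(record$patient_name),
           record$patient_id, record$birth_date, record$address, record$phone,
           record$accession_numbers, record$referring_physician,
           record$performing_physician, record$institution,
           record$study_dates, record$aux))
}

#' Generate a collision-free cohort of identities
#'
#' Draws one [make_phi_record()] per patient and guarantees that no
#' identity-bearing string (names, IDs, dates, accession numbers, tokens) is
#' shared between two records or duplicated within one, re-drawing a record
#' with a salted sub-seed in the rare event of a collision. Deterministic for
#' fixed inputs.
#'
#' @param seed Integer master seed.
#' @param n_studies Integer vector: studies per patient (length = cohort
#'   size).
#' @return List of `phi_record` objects.
#' @export
make_phi_corpus <- function(seed, n_studies) {
  records <- vector("list", length(n_studies))
  seen <- character(0)
  for (i in seq_along(n_studies)) {
    for (salt in 0:100) {
      rec <- make_phi_record(seed, i - 1L, n_studies[i], salt = salt)
      vals <- record_span_values(rec)
      if (!anyDuplicated(vals) && !any(vals %in% seen)) break
      rec <- NULL
    }
    if (is.null(rec)) fail_with("could not draw a collision-free identity for patient %d", i)
    records[[i]] <- rec
    seen <- c(seen, record_span_values(rec))
  }
  records
}

# --- payload templates ----------------------------------------------------

PHI_FIELD_REFS <- c(
  "patient_name", "display_name", "patient_id", "birth_date",
  "address", "phone", "accession_number", "referring_physician",
  "performing_physician", "institution", "study_date", "comments_seed",
  paste0("aux:", c("name_caps", "name_comma", "name_short",
                   "institution_caps", "operator_name", "order_note",
                   "serial_no", "department", "coil_token", "batch_token",
                   "mao_token", "svc_token", "img_token", "ae_token",
                   "detector_token", "subtype_token", "station_token",
                   "admit_token", "deriv_token", "req_token", "struct_token",
                   "imaging_token", "toshiba_token", "kanji_token",
                   "recv_token", "phoenix_token", "start_token",
                   "series_token", "sched_date", "struct_date")))

resolve_phi_ref <- function(ref, record, study_index = 1L) {
  if (startsWith(ref, "aux:")) {
    key <- sub("^aux:", "", ref)
    if (!key %in% names(record$aux) || is.na(record$aux[[key]])) {
      fail_with("unresolvable PHI field reference: %s", ref)
    }
    return(unname(record$aux[[key]]))
  }
  switch(ref,
    patient_name = record$patient_name,
    display_name = pn_display(record$patient_name),
    patient_id = record$patient_id,
    birth_date = record$birth_date,
    sex = record$sex,
    address = record$address,
    phone = record$phone,
    institution = record$institution,
    comments_seed = record$comments_seed,
    accession_number = record$accession_numbers[
      min(study_index, length(record$accession_numbers))],
    referring_physician = record$referring_physician[
      min(study_index, length(record$referring_physician))],
    performing_physician = record$performing_physician[
      min(study_index, length(record$performing_physician))],
    study_date = record$study_dates[
      min(study_index, length(record$study_dates))],
    fail_with("unresolvable PHI field reference: %s", ref)
  )
}

#' Payload templates
#'
#' A `payload_template` describes how one attribute value is assembled from
#' PHI field references and retained clinically useful text. Mixed templates
#' carry both, modelling values like a study description that embeds a
#' patient name next to the exam code.
#'
#' @param target Tag-notation string for the attribute the payload is meant
#'   for.
#' @param template_id Short identifier.
#' @param phi_refs Character vector of PHI field references (may be empty).
#' @param retained_pool Pool of retained-text candidates (may be empty); one
#'   is chosen per rendering, rotating with the study index.
#' @param assembly `"phi_first"` or `"retained_first"`.
#' @return A `payload_template`.
#' @export
payload_template <- function(target, template_id, phi_refs = character(0),
                             retained_pool = character(0),
                             assembly = c("phi_first", "retained_first")) {
  assembly <- match.arg(assembly)
  if (!length(phi_refs) && !length(retained_pool)) {
    fail_with("template %s needs phi_refs or retained text", template_id)
  }
  structure(list(target = target, template_id = template_id,
                 phi_refs = phi_refs, retained_pool = retained_pool,
                 assembly = assembly),
            class = "payload_template")
}

#' Load the template catalogue
#'
#' The bundled catalogue covers every unusual standard attribute and every
#' private attribute in the injection target lists. Columns: `target`,
#' `template_id`, `phi_refs` (`|`-separated), `retained_pool`
#' (`|`-separated), `assembly`.
#'
#' @param path Catalogue CSV; defaults to the bundled file.
#' @return List of `payload_template` objects, named by `template_id`.
#' @export
load_templates <- function(path = pkg_extdata("payload_templates.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i) {
    split_pool <- function(x) if (!nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
    payload_template(df$target[i], df$template_id[i],
                     split_pool(df$phi_refs[i]), split_pool(df$retained_pool[i]),
                     df$assembly[i])
  })
  names(out) <- df$template_id
  out
}

#' Render a payload from a template and a record
#'
#' Resolves the template's PHI references against the record, picks a
#' retained-text fragment from the pool, and assembles the value. The value
#' contains every reported span as a substring and the PHI and retained
#' spans never overlap.
#'
#' @param template A [payload_template].
#' @param record A `phi_record`.
#' @param study_index 1-based study index used for per-study fields.
#' @return List with `value`, `phi_spans`, `retained_spans`.
#' @export
render_payload <- function(template, record, study_index = 1L) {
  phi <- vapply(template$phi_refs, resolve_phi_ref, character(1),
                record = record, study_index = study_index)
  retained <- character(0)
  if (length(template$retained_pool)) {
    retained <- template$retained_pool[
      ((study_index - 1L) %% length(template$retained_pool)) + 1L]
  }
  parts <- if (template$assembly == "phi_first") c(phi, retained) else c(retained, phi)
  value <- paste(parts, collapse = " ")
  check_spans(value, phi, retained)
  list(value = value, phi_spans = unname(phi), retained_spans = retained)
}

# Verify every span occurs in the value and that PHI and retained spans can
# be located without overlapping. Longer spans claim positions first so a
# short span cannot squat inside a longer one's only occurrence.
check_spans <- function(value, phi, retained) {
  used <- integer(0)
  spans <- c(phi, retained)
  spans <- spans[order(nchar(spans), decreasing = TRUE)]
  for (s in spans) {
    hits <- gregexpr(s, value, fixed = TRUE)[[1]]
    if (hits[1] == -1L) fail_with("rendered span not found in value: %s", s)
    placed <- FALSE
    for (h in hits) {
      span <- seq.int(h, h + nchar(s) - 1L)
      if (!any(span %in% used)) {
        used <- c(used, span)
        placed <- TRUE
        break
      }
    }
    if (!placed) fail_with("overlapping spans in rendered payload: %s", s)
  }
  invisible(TRUE)
}
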