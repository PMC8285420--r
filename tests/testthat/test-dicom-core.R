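test_that("tag notation parses and round-trips for standard and private forms", {
  t1 <- parse_tag("(0010,0010)")
  expect_equal(t1$group, 0x0010L)
  expect_equal(t1$element, 0x0010L)
  expect_false(is_private_tag(t1))

  t2 <- parse_tag('(0009,"GEMS_PETD_01",37)')
  expect_true(is_private_tag(t2))
  expect_equal(t2$creator, "GEMS_PETD_01")
  expect_equal(t2$private_byte, 0x37L)

  for (txt in c("(0010,0010)", '(0009,"GEMS_PETD_01",37)', "(7fe0,0010)",
                '(3f01,"INTELERAD MEDICAL SYSTEMS",03)')) {
    expect_identical(format_tag(parse_tag(format_tag(parse_tag(txt)))),
                     format_tag(parse_tag(txt)))
  }

  expect_error(parse_tag("(0010,0010"), "malformed")
  expect_error(parse_tag("(00XX,0010)"), "malformed")
  expect_error(parse_tag('(0008,"CREATOR",10)'), "even group")
  expect_error(tag_path(0x0009, creator = "X", private_byte = 0x100),
               "0x00, 0xFF")
})

test_that("private resolution honours creator reservations and is deterministic", {
  inst <- new_instance()
  inst <- set_element(inst, tag_path(0x0009, 0x0010), "FDMS 1.0", "LO")
  inst <- set_element(inst, tag_path(0x0009, 0x1092), "RADIOLOGY", "LO")
  el <- resolve_private(inst, parse_tag('(0009,"FDMS 1.0",92)'))
  expect_equal(el$element, 0x1092L)
  expect_equal(el$value, "RADIOLOGY")
  expect_identical(el, resolve_private(inst, parse_tag('(0009,"FDMS 1.0",92)')))

  # absent when no odd-group elements exist at all
  empty <- new_instance()
  expect_null(resolve_private(empty, parse_tag('(0009,"FDMS 1.0",92)')))

  # two creators in one group: brute-force reservation scan as oracle
  inst2 <- new_instance()
  inst2 <- set_element(inst2, tag_path(0x0009, 0x0010), "CREATOR_A", "LO")
  inst2 <- set_element(inst2, tag_path(0x0009, 0x0011), "CREATOR_B", "LO")
  inst2 <- set_element(inst2, tag_path(0x0009, 0x1037), "a-value", "LO")
  inst2 <- set_element(inst2, tag_path(0x0009, 0x1137), "b-value", "LO")
  oracle_block <- NULL
  for (xx in 0x10:0xFF) {
    v <- get_value(inst2, tag_path(0x0009, xx))
    if (!is.null(v) && v == "CREATOR_B") oracle_block <- xx
  }
  expect_equal(oracle_block, 0x11)
  el_b <- resolve_private(inst2, parse_tag('(0009,"CREATOR_B",37)'))
  expect_equal(el_b$element, oracle_block * 256L + 0x37L)
  expect_equal(el_b$value, "b-value")
  # never resolves through the wrong creator
  el_a <- resolve_private(inst2, parse_tag('(0009,"CREATOR_A",37)'))
  expect_equal(el_a$value, "a-value")
})

test_that("Part-10 round-trip is lossless and serialization deterministic", {
  set.seed(42)
  for (modality in c("CT", "MR", "MG")) {
    inst <- build_instance(test_node(modality), seed = 7, matrix_size = 48)
    inst <- set_element(inst, parse_tag('(0009,"GEMS_PETD_01",37)'), "payload")
    raw1 <- write_instance(inst)
    back <- read_instance(raw1)
    expect_identical(back$elements, inst$elements)
    expect_identical(inst_pixels(back), inst_pixels(inst))
    expect_identical(write_instance(back), raw1)
  }
})

test_that("serialized element tags are strictly increasing", {
  inst <- build_instance(test_node("CT"), seed = 1, matrix_size = 48)
  raw <- write_instance(inst)
  back <- read_instance(raw)
  keys <- names(back$elements)
  nums <- strtoi(substr(keys, 1, 4), 16L) * 65536 + strtoi(substr(keys, 5, 8), 16L)
  expect_true(all(diff(nums) > 0))
})

test_that("unsupported-VR elements survive as opaque bytes, byte-identically", {
  inst <- build_instance(test_node("CT"), seed = 1, matrix_size = 48)
  payload <- as.raw(c(1, 2, 254, 255, 0, 9, 17, 128))
  inst <- set_element(inst, tag_path(0x0018, 0x9087), payload, vr = "FD")
  inst <- set_element(inst, tag_path(0x0008, 0x1110), raw(0), vr = "SQ")
  raw1 <- write_instance(inst)
  back <- read_instance(raw1)
  expect_identical(get_value(back, tag_path(0x0018, 0x9087)), payload)
  expect_identical(get_element(back, tag_path(0x0018, 0x9087))$vr, "FD")
  expect_identical(write_instance(back), raw1)
})

test_that("malformed streams and invalid values are rejected", {
  expect_error(read_instance(as.raw(rep(0, 200))), "DICM")
  inst <- build_instance(test_node("CT"), seed = 1, matrix_size = 48)
  raw1 <- write_instance(inst)
  corrupted <- raw1
  corrupted[129:132] <- charToRaw("XXXX")
  expect_error(read_instance(corrupted), "DICM")

  # wrong transfer syntax is an explicit unsupported-format error
  bad_meta <- c(
    raw(128), charToRaw("DICM"),
    deidbench:::encode_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2"),
    deidbench:::encode_element(0x0008, 0x0060, "CS", "CT"))
  expect_error(read_instance(bad_meta), "transfer syntax")

  # invalid calendar date refused before write
  bad <- try(set_element(inst, tag_path(0x0008, 0x0020), "20130230", "DA"),
             silent = TRUE)
  expect_true(inherits(bad, "try-error"))
  inst$elements[["00080020"]] <- list(group = 0x0008L, element = 0x0020L,
                                      vr = "DA", value = "20130230")
  expect_error(write_instance(inst), "DA")
})

test_that("a 128x128 16-bit instance carries a 32768-byte pixel payload", {
  inst <- build_instance(test_node("CT"), seed = 2, matrix_size = 128)
  raw1 <- write_instance(inst)
  pix_el <- deidbench:::encode_element(0x7FE0, 0x0010, "OW", inst_pixels(inst))
  expect_equal(length(pix_el) - 12L, 128L * 128L * 2L)
  # pixel data is the last element, so the stream must end with it
  expect_identical(raw1[(length(raw1) - length(pix_el) + 1L):length(raw1)],
                   pix_el)
})

test_that("attribute types match the shipped table, with modality overriding All", {
  expect_equal(attribute_type("CT", "(0008,0008)"), "T1")
  expect_equal(attribute_type("CT", "(0018,0060)"), "T2")
  expect_equal(attribute_type("MG", "(0020,0060)"), "T2C")
  expect_equal(attribute_type("CT", "(0018,9999)"), "not_profiled")

  # exhaustive lookup oracle over every (modality, tag) pair in the table
  profiles <- load_modality_profiles()
  for (m in c("CT", "MR", "PT", "DX", "CR", "MG")) {
    tags <- unique(profiles$tag)
    for (tg in tags) {
      norm <- vapply(profiles$tag, function(t) format_tag(parse_tag(t)), character(1))
      mine <- norm == format_tag(parse_tag(tg))
      row <- profiles[mine & profiles$modality == m, , drop = FALSE]
      if (!nrow(row)) row <- profiles[mine & profiles$modality == "All", , drop = FALSE]
      want <- if (nrow(row)) paste0("T", row$type[1]) else "not_profiled"
      expect_identical(attribute_type(m, tg), want)
    }
  }
})

test_that("files written here are readable by an independent DICOM implementation", {
  inst <- build_instance(test_node("MR"), seed = 9, matrix_size = 48)
  inst <- set_element(inst, parse_tag('(0009,"GEMS_PETD_01",37)'), "BatchX")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_file(inst, path)
  script <- paste(
    "import pydicom, sys",
    sprintf("d = pydicom.dcmread(r'%s')", path),
    "px = d.pixel_array",
    "print(d.Modality, d[0x0009,0x1037].value, px.shape[0], px.shape[1], int(px[4,6]), int(px.max()))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  px <- inst_pixels(inst)
  expect_identical(parts[1], "MR")
  expect_identical(parts[2], "BatchX")
  expect_equal(as.integer(parts[3:4]), dim(px))
  expect_equal(as.integer(parts[5]), px[5, 7])
  expect_equal(as.integer(parts[6]), max(px))
})
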