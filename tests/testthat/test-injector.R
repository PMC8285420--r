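test_that("set_tag overwrites scope-wide, auto-reserves private blocks, allows empties", {
  pipe <- small_pipeline()
  ds <- pipe$clean
  pid <- ds$meta$patient_id[1]
  d <- injection_directive("Patient", pid, "set_tag", "(0010,0010)",
                           list(value = "ROGERS^BILLY"))
  out <- apply_set_tag(ds, d)
  in_scope <- ds$meta$instance_uid[ds$meta$patient_id == pid]
  expect_setequal(out$op$affected_instances, in_scope)
  for (u in in_scope) {
    expect_identical(get_value(out$dataset$instances[[u]], parse_tag("(0010,0010)")),
                     "ROGERS^BILLY")
  }

  dp <- injection_directive("Instance", ds$meta$instance_uid[1], "set_tag",
                            '(0009,"GEMS_PETD_01",37)', list(value = "BATCH"))
  out2 <- apply_set_tag(ds, dp)
  inst <- out2$dataset$instances[[ds$meta$instance_uid[1]]]
  el <- resolve_private(inst, parse_tag('(0009,"GEMS_PETD_01",37)'))
  expect_identical(el$value, "BATCH")
  # creator reservation element written alongside
  expect_identical(get_value(inst, tag_path(0x0009, el$element %/% 256L)),
                   "GEMS_PETD_01")

  de <- injection_directive("Instance", ds$meta$instance_uid[1], "set_tag",
                            "(0008,1030)", list(value = ""))
  out3 <- apply_set_tag(ds, de)
  el3 <- get_element(out3$dataset$instances[[ds$meta$instance_uid[1]]],
                     parse_tag("(0008,1030)"))
  expect_false(is.null(el3))
  expect_identical(el3$value, "")

  bad <- injection_directive("Patient", pid, "set_tag", "(0010,0030)",
                             list(value = "not-a-date"))
  expect_error(apply_set_tag(ds, bad), "DA")
})

test_that("delete_tag removes, is an idempotent no-op when absent, refuses Type 1", {
  pipe <- small_pipeline()
  ds <- pipe$clean
  u <- ds$meta$instance_uid[1]
  ds$instances[[u]] <- set_element(ds$instances[[u]], parse_tag("(0010,4000)"),
                                   "some comment")
  d <- injection_directive("Instance", u, "delete_tag", "(0010,4000)")
  out <- apply_delete_tag(ds, d)
  expect_null(get_element(out$dataset$instances[[u]], parse_tag("(0010,4000)")))
  expect_equal(out$op$affected_instances, u)

  out2 <- apply_delete_tag(out$dataset, d)
  expect_length(out2$op$affected_instances, 0L)

  t1 <- injection_directive("Instance", u, "delete_tag", "(0008,0016)")
  expect_error(apply_delete_tag(ds, t1), "Type 1")
})

test_that("shift_date offsets scoped dates consistently and logs zero shifts", {
  pipe <- small_pipeline()
  ds <- pipe$clean
  su <- ds$meta$study_uid[1]
  before <- get_value(ds$instances[[ds$meta$instance_uid[1]]],
                      parse_tag("(0008,0020)"))
  d <- injection_directive("Study", su, "shift_date", "(0008,0020)",
                           list(days = 30L))
  out <- apply_shift_date(ds, d)
  vals <- unique(vapply(out$op$affected_instances, function(u) {
    get_value(out$dataset$instances[[u]], parse_tag("(0008,0020)"))
  }, character(1)))
  expect_identical(vals, shift_date(before, 30))
  expect_identical(out$op$before_value, before)

  z <- apply_shift_date(ds, injection_directive("Study", su, "shift_date",
                                                "(0008,0020)", list(days = 0L)))
  expect_identical(z$op$after_value, before)
  expect_true(length(z$op$affected_instances) > 0)

  nb <- injection_directive("Study", su, "shift_date", "(0008,0060)",
                            list(days = 3L))
  expect_error(apply_shift_date(ds, nb), "DA")
})

test_that("substitute only overwrites existing non-empty values, recording skips", {
  pipe <- small_pipeline()
  ds <- pipe$clean
  su <- ds$meta$study_uid[1]
  d <- injection_directive("Study", su, "substitute", "(0008,1030)",
                           list(value = "Billy Rogers XR CHEST AP PORTABLE",
                                phi_spans = "Billy Rogers",
                                retained_spans = "XR CHEST AP PORTABLE"))
  out <- apply_substitute(ds, d)
  expect_true(length(out$op$affected_instances) > 0)
  expect_identical(out$op$phi_spans, "Billy Rogers")
  expect_identical(out$op$retained_spans, "XR CHEST AP PORTABLE")

  # absent tag everywhere: zero affected, all skipped, no error
  d2 <- injection_directive("Study", su, "substitute", "(0018,7006)",
                            list(value = "x", phi_spans = "x"))
  out2 <- apply_substitute(ds, d2)
  expect_length(out2$op$affected_instances, 0L)
  expect_length(out2$op$phi_spans, 0L)
  expect_setequal(out2$op$skipped_instances,
                  ds$meta$instance_uid[ds$meta$study_uid == su])
})

test_that("string_replace counts replacements and tolerates degenerate inputs", {
  pipe <- small_pipeline()
  ds <- pipe$clean
  u <- ds$meta$instance_uid[1]
  ds$instances[[u]] <- set_element(ds$instances[[u]], parse_tag("(0008,1030)"),
                                   "XR CHEST AP PORTABLE")
  d <- injection_directive("Instance", u, "string_replace", "(0008,1030)",
                           list(old = "PORTABLE", new = "Billy Rogers PORTABLE",
                                phi_spans = "Billy Rogers"))
  out <- apply_string_replace(ds, d)
  expect_equal(out$op$n_replacements, 1L)
  expect_identical(get_value(out$dataset$instances[[u]], parse_tag("(0008,1030)")),
                   "XR CHEST AP Billy Rogers PORTABLE")

  d2 <- injection_directive("Instance", u, "string_replace", "(0008,1030)",
                            list(old = "ABSENT", new = "Y"))
  out2 <- apply_string_replace(ds, d2)
  expect_equal(out2$op$n_replacements, 0L)
  expect_identical(get_value(out2$dataset$instances[[u]], parse_tag("(0008,1030)")),
                   "XR CHEST AP PORTABLE")

  d3 <- injection_directive("Instance", u, "string_replace", "(0008,1030)",
                            list(old = "CHEST", new = "CHEST"))
  out3 <- apply_string_replace(ds, d3)
  expect_equal(out3$op$n_replacements, 1L)
  expect_identical(get_value(out3$dataset$instances[[u]], parse_tag("(0008,1030)")),
                   "XR CHEST AP PORTABLE")
})

test_that("pixel burn-in touches only glyph pixels inside the rectangle", {
  pipe <- small_pipeline()
  ds <- pipe$clean
  u <- ds$meta$instance_uid[1]
  before_px <- inst_pixels(ds$instances[[u]])
  before_els <- ds$instances[[u]]$elements
  d <- injection_directive("Instance", u, "annotate_img", NULL,
                           list(text = "ROGERS^BILLY\n19430722",
                                rect = c(8L, 8L, 26L, 88L)))
  out <- apply_annotate_img(ds, d)
  after_px <- inst_pixels(out$dataset$instances[[u]])
  region <- after_px[9:26, 9:88]
  expect_true(any(region == 65535L))
  # outside the rect: bit-identical
  outside <- after_px
  outside[9:26, 9:88] <- before_px[9:26, 9:88]
  expect_identical(outside, before_px)
  # inside the rect, non-glyph pixels untouched
  changed <- after_px != before_px
  expect_true(all(after_px[changed] == 65535L))
  # header unchanged except pixel element
  after_els <- out$dataset$instances[[u]]$elements
  after_els[["7FE00010"]] <- before_els[["7FE00010"]]
  expect_identical(after_els, before_els)

  # empty text: zero pixels changed but still logged
  e <- apply_annotate_img(ds, injection_directive(
    "Instance", u, "annotate_img", NULL, list(text = "", rect = c(0L, 0L, 8L, 8L))))
  expect_identical(inst_pixels(e$dataset$instances[[u]]), before_px)
  expect_equal(e$op$affected_instances, u)

  # multi-line text stacks with fixed leading: two lines burn strictly more
  # rows than one
  one <- apply_annotate_img(ds, injection_directive(
    "Instance", u, "annotate_img", NULL,
    list(text = "AB", rect = c(8L, 8L, 40L, 40L))))
  two <- apply_annotate_img(ds, injection_directive(
    "Instance", u, "annotate_img", NULL,
    list(text = "AB\nCD", rect = c(8L, 8L, 40L, 40L))))
  rows_burned <- function(res) {
    px <- inst_pixels(res$dataset$instances[[u]])
    sum(apply(px == 65535L, 1, any))
  }
  expect_equal(rows_burned(two), 2L * rows_burned(one))

  expect_error(apply_annotate_img(ds, injection_directive(
    "Instance", u, "annotate_img", NULL,
    list(text = "X", rect = c(0L, 0L, 8L, 500L)))), "rect exceeds")
  expect_error(apply_annotate_img(ds, injection_directive(
    "Instance", u, "annotate_img", NULL,
    list(text = "TOOLONGFORRECT", rect = c(0L, 0L, 8L, 20L)))), "does not fit")
})

test_that("plans run deterministically, in order, with locality", {
  pipe <- small_pipeline()
  ds <- pipe$clean
  res1 <- run_plan(ds, pipe$plan)
  expect_identical(
    lapply(res1$dataset$instances, write_instance),
    lapply(pipe$injected$instances, write_instance))

  # empty plan: byte-identical output
  res0 <- run_plan(ds, list())
  expect_identical(lapply(res0$dataset$instances, write_instance),
                   lapply(ds$instances, write_instance))

  # order invariance for operations on disjoint (instance, tag) pairs
  u1 <- ds$meta$instance_uid[1]
  u2 <- ds$meta$instance_uid[2]
  d1 <- injection_directive("Instance", u1, "set_tag", "(0008,1010)",
                            list(value = "STN1"))
  d2 <- injection_directive("Instance", u2, "set_tag", "(0018,1000)",
                            list(value = "SN1"))
  a <- run_plan(ds, list(d1, d2))$dataset
  b <- run_plan(ds, list(d2, d1))$dataset
  expect_identical(lapply(a$instances, write_instance),
                   lapply(b$instances, write_instance))

  # first failing directive aborts with a positional error
  bad <- injection_directive("Patient", "NOSUCH", "set_tag", "(0010,0010)",
                             list(value = "X^Y"))
  expect_error(run_plan(ds, list(d1, bad)), "directive 2")
})

test_that("injected datasets stay profile compliant and localize edits", {
  pipe <- small_pipeline()
  expect_equal(nrow(validate_profile_compliance(pipe$injected)), 0L)

  # locality: per instance, only planned tags (plus pixels) differ from clean
  planned_tags <- unique(vapply(pipe$provenance, function(op) {
    if (is.null(op$directive$tag)) "pixels" else
      format_tag(parse_tag(op$directive$tag))
  }, character(1)))
  for (u in pipe$clean$meta$instance_uid) {
    clean_inst <- pipe$clean$instances[[u]]
    inj_inst <- pipe$injected$instances[[u]]
    keys <- union(names(clean_inst$elements), names(inj_inst$elements))
    for (k in keys) {
      same <- identical(clean_inst$elements[[k]], inj_inst$elements[[k]])
      if (!same) {
        grp <- strtoi(substr(k, 1, 4), 16L)
        el <- strtoi(substr(k, 5, 8), 16L)
        tag_txt <- if (grp == 0x7FE0) "pixels" else
          format_tag(tag_path(grp, el))
        is_creator <- grp %% 2L == 1L && el >= 0x10L && el <= 0xFFL
        is_private_target <- grp %% 2L == 1L && el > 0xFFL
        expect_true(tag_txt %in% planned_tags || is_creator || is_private_target,
                    label = sprintf("unexpected change at %s in %s", k, u))
      }
    }
  }
})

test_that("plan files round-trip through JSON lines", {
  pipe <- small_pipeline()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_plan(pipe$plan, path)
  back <- read_plan(path)
  expect_equal(length(back), length(pipe$plan$directives))
  for (i in seq_along(back)) {
    d0 <- pipe$plan$directives[[i]]
    d1 <- back[[i]]
    expect_identical(d1$scope, d0$scope)
    expect_identical(d1$selector, d0$selector)
    expect_identical(d1$op, d0$op)
    expect_identical(d1$tag, d0$tag)
  }
  # provenance log round-trips too
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_provenance(pipe$provenance, p2)
  prov <- read_provenance(p2)
  expect_equal(length(prov), length(pipe$provenance))
  expect_identical(lapply(prov, `[[`, "phi_spans"),
                   lapply(pipe$provenance, `[[`, "phi_spans"))
  expect_identical(vapply(prov, `[[`, character(1), "final_selector"),
                   vapply(pipe$provenance, `[[`, character(1), "final_selector"))
})
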