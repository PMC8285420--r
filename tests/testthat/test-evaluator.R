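test_that("scope resolution maps original identifiers through the crosswalks", {
  pipe <- small_pipeline()
  orc <- pipe$oracle
  rec1 <- pipe$plan$records[[1]]
  e <- answer_key_entry("Patient", rec1$patient_id, "(0010,0010)",
                        "Patient's Name", "text_removed", rec1$patient_name)
  uids <- resolve_scope(e, orc$dataset, orc$patient_xwalk, orc$uid_xwalk)
  new_pid <- unname(orc$patient_xwalk[rec1$patient_id])
  expect_setequal(uids, orc$dataset$meta$instance_uid[
    orc$dataset$meta$patient_id == new_pid])

  # unknown series: unresolvable
  e2 <- answer_key_entry("Series", "1.2.3.404", "(0020,000e)",
                         "Series Instance UID", "uid_changed", "1.2.3.404")
  expect_null(resolve_scope(e2, orc$dataset, orc$patient_xwalk, orc$uid_xwalk))
  r <- check_entry(e2, orc$dataset, NULL)
  expect_identical(r$status, "unresolvable")
  expect_match(r$evidence, "resolves to no instances")

  # instance scope selects exactly one instance
  iu <- pipe$injected$meta$instance_uid[1]
  e3 <- answer_key_entry("Instance", iu, "(0008,0018)", "SOP Instance UID",
                         "uid_changed", iu)
  expect_length(resolve_scope(e3, orc$dataset, orc$patient_xwalk, orc$uid_xwalk), 1L)
})

test_that("check semantics match the action definitions", {
  pipe <- small_pipeline()
  ds <- pipe$injected
  rec1 <- pipe$plan$records[[1]]
  idd <- pipe$identity
  # text_removed vs a value still holding the span: fail with evidence
  e <- answer_key_entry("Patient", rec1$patient_id, "(0010,0010)",
                        "Patient's Name", "text_removed", rec1$patient_name)
  uids <- resolve_scope(e, ds, idd$patient_xwalk, idd$uid_xwalk)
  r <- check_entry(e, ds, uids)
  expect_identical(r$status, "fail")
  expect_match(r$evidence, rec1$patient_name, fixed = TRUE)

  # deleting the tag satisfies removal
  ds2 <- ds
  for (u in uids) {
    ds2$instances[[u]] <- delete_element(ds2$instances[[u]],
                                         parse_tag("(0010,0010)"))
  }
  expect_identical(check_entry(e, ds2, uids)$status, "pass")

  # date_shifted passes exactly when value == shift_date(original, days)
  de <- answer_key_entry("Study", "S", "(0008,0020)", "Study Date",
                         "date_shifted", "19430722")
  mini <- new_dataset(list(local({
    i <- build_instance(test_node("CT"), 1, 48)
    set_element(i, parse_tag("(0008,0020)"), "19430708", "DA")
  })))
  u <- mini$meta$instance_uid
  expect_identical(check_entry(de, mini, u, list(expected_days = -14L))$status,
                   "pass")
  expect_identical(check_entry(de, mini, u, list(expected_days = -13L))$status,
                   "fail")
  expect_identical(check_entry(de, mini, u, list(expected_days = 0L))$status,
                   "fail")
  expect_identical(check_entry(de, mini, u, list(expected_days = NA_integer_))$status,
                   "fail")
})

test_that("oracle output scores a perfect report; identity fails every transformation check", {
  pipe <- small_pipeline()
  orc <- pipe$oracle
  rep_orc <- evaluate_dataset(orc$dataset, pipe$key, orc$patient_xwalk,
                              orc$uid_xwalk)
  expect_true(rep_orc$overall_pass)
  expect_equal(nrow(rep_orc$leaks), 0L)
  expect_true(all(report_status(rep_orc) == "pass"))

  idd <- pipe$identity
  rep_id <- evaluate_dataset(idd$dataset, pipe$key, idd$patient_xwalk,
                             idd$uid_xwalk)
  st <- report_status(rep_id)
  act <- report_actions(rep_id)
  must_fail <- c("text_removed", "date_shifted", "uid_changed", "pixels_hidden")
  must_pass <- c("tag_retained", "text_retained", "text_notnull")
  expect_true(all(st[act %in% must_fail] == "fail"))
  expect_true(all(st[act %in% must_pass] == "pass"))
  expect_false(rep_id$overall_pass)
  # fixed-shift mode agrees with inference on the oracle output
  rep_fx <- evaluate_dataset(orc$dataset, pipe$key, orc$patient_xwalk,
                             orc$uid_xwalk, shift_mode = "fixed",
                             shift_table = orc$shift_table)
  expect_true(rep_fx$overall_pass)
})

test_that("each single-fault oracle variant fails exactly its action class", {
  pipe <- small_pipeline()
  cases <- list(skip_burnin = "pixels_hidden", skip_private = "text_removed",
                unshifted_dates = "date_shifted", reuse_uids = "uid_changed")
  for (f in names(cases)) {
    orc <- build_oracle_deid(pipe$injected, pipe$key, seed = 99, faults = f)
    rep <- evaluate_dataset(orc$dataset, pipe$key, orc$patient_xwalk,
                            orc$uid_xwalk)
    st <- report_status(rep)
    act <- report_actions(rep)
    expect_identical(unique(act[st == "fail"]), cases[[f]],
                     label = sprintf("fault %s fail classes", f))
    if (f == "skip_private") {
      bad <- rep$results[st == "fail"]
      tags <- unique(vapply(bad, function(r) r$entry$tag, character(1)))
      expect_length(tags, 1L)
      expect_true(is_private_tag(parse_tag(tags)))
    }
  }
})

test_that("leak scanning finds planted PHI anywhere, including un-keyed tags", {
  pipe <- small_pipeline()
  # unmodified evaluation dataset: every injected span is found at least once
  spans <- unlist(lapply(pipe$provenance, `[[`, "phi_spans"))
  found <- scan_leakage(pipe$injected, spans, key = pipe$key)
  expect_setequal(unique(found$phi), unique(spans))

  # clean dataset: zero hits against the same corpus
  expect_equal(nrow(scan_leakage(pipe$clean, spans)), 0L)

  # a buggy de-identifier copying PHI into an un-keyed tag is still caught
  orc <- pipe$oracle
  buggy <- orc$dataset
  u <- buggy$meta$instance_uid[1]
  rec1 <- pipe$plan$records[[1]]
  buggy$instances[[u]] <- set_element(buggy$instances[[u]],
                                      parse_tag("(0008,103E)"),
                                      paste("copy of", rec1$patient_name))
  lk <- scan_leakage(buggy, spans, key = pipe$key, uid_xwalk = orc$uid_xwalk)
  expect_true(rec1$patient_name %in% lk$phi)
  expect_true("(0008,103e)" %in% lk$location)
})

test_that("evaluation is invariant under crosswalk relabeling and deterministic", {
  pipe <- small_pipeline()
  orc <- pipe$oracle
  rep1 <- evaluate_dataset(orc$dataset, pipe$key, orc$patient_xwalk,
                           orc$uid_xwalk)
  rep2 <- evaluate_dataset(orc$dataset, pipe$key, orc$patient_xwalk,
                           orc$uid_xwalk)
  expect_identical(report_status(rep1), report_status(rep2))
  expect_identical(rep1$leaks, rep2$leaks)

  # relabel every de-identified patient ID consistently in data + crosswalk
  relabel <- stats::setNames(sprintf("Z-%02d", seq_along(orc$patient_xwalk)),
                             unname(orc$patient_xwalk))
  ds <- orc$dataset
  for (u in names(ds$instances)) {
    old <- inst_patient_id(ds$instances[[u]])
    ds$instances[[u]] <- set_element(ds$instances[[u]], tag_path(0x0010, 0x0020),
                                     unname(relabel[old]), "LO")
  }
  ds <- deidbench:::refresh_meta(ds)
  px <- stats::setNames(unname(relabel[unname(orc$patient_xwalk)]),
                        names(orc$patient_xwalk))
  rep3 <- evaluate_dataset(ds, pipe$key, px, orc$uid_xwalk)
  expect_identical(report_status(rep3), report_status(rep1))
  expect_true(rep3$overall_pass)
})

test_that("removing extra non-keyed optional attributes never breaks a passing check", {
  pipe <- small_pipeline()
  orc <- pipe$oracle
  # plant an optional attribute no key entry references, confirm the run
  # passes with it, then delete it everywhere: still passing
  keyed <- unique(stats::na.omit(vapply(pipe$key, `[[`, character(1), "tag")))
  extra <- "(0008,0021)"  # Series Date: optional, outside the profiles
  stopifnot(!extra %in% keyed)
  ds <- orc$dataset
  for (u in names(ds$instances)) {
    ds$instances[[u]] <- set_element(ds$instances[[u]], parse_tag(extra),
                                     "20240401", "DA")
  }
  rep_with <- evaluate_dataset(ds, pipe$key, orc$patient_xwalk, orc$uid_xwalk)
  expect_true(rep_with$overall_pass)
  for (u in names(ds$instances)) {
    ds$instances[[u]] <- delete_element(ds$instances[[u]], parse_tag(extra))
  }
  rep_without <- evaluate_dataset(ds, pipe$key, orc$patient_xwalk, orc$uid_xwalk)
  expect_true(rep_without$overall_pass)
  expect_identical(report_status(rep_without), report_status(rep_with))
})

test_that("report accounting sums to the key size", {
  pipe <- small_pipeline()
  idd <- pipe$identity
  rep <- evaluate_dataset(idd$dataset, pipe$key, idd$patient_xwalk,
                          idd$uid_xwalk)
  total <- sum(vapply(rep$per_action_counts, sum, numeric(1)))
  expect_equal(total, length(pipe$key))
  expect_false(rep$overall_pass)
  # all pass and no leaks => overall pass
  ok <- summarize_results(
    list(deidbench:::check_result(pipe$key[[1]], "pass")),
    scan_leakage(pipe$oracle$dataset, character(0)))
  expect_true(ok$overall_pass)
})
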