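enc1 <- list(case_id = "C1", patient_id = "P1",
             admit_ts = ts0(0), discharge_ts = ts0(240))

mk_aki <- function(stage = 2L, second_h = 100, patient_id = NULL) {
  f <- list(stage = stage, criterion = "ratio_7d", first_value = 100,
            second_value = 100 * (stage + 0.5), first_ts = ts0(second_h - 48),
            second_ts = ts0(second_h), interval_hours = 48,
            patient_id = patient_id)
  class(f) <- "aki_finding"
  f
}

mk_ckd <- function(stage = 3L, end_h = 120) {
  f <- list(stage = stage, window_start_ts = ts0(end_h - 2400),
            window_end_ts = ts0(end_h), span_hours = 2400, n_values = 3L,
            max_egfr_in_window = 50, acr = NULL, evidence = "egfr_window")
  class(f) <- "ckd_finding"
  f
}

test_that("acute-on-chronic is flagged exactly when both findings are present", {
  expect_false(combine_diagnoses(mk_aki(), NULL, enc1)$acute_on_chronic)
  expect_false(combine_diagnoses(NULL, mk_ckd(), enc1)$acute_on_chronic)
  expect_true(combine_diagnoses(mk_aki(1L), mk_ckd(3L), enc1)$acute_on_chronic)
  empty <- combine_diagnoses(NULL, NULL, enc1, map = default_icd_map())
  expect_false(empty$acute_on_chronic)
  expect_length(empty$icd_codes, 0)
})

test_that("the detection date is the latest contributing measurement clamped to the stay", {
  ds <- combine_diagnoses(mk_aki(2L, second_h = 100), mk_ckd(3L, end_h = 120), enc1)
  expect_equal(ds$detection_date, as.Date(ts0(120), tz = "UTC"))
  # a window ending before admission clamps to the admission date
  ds2 <- combine_diagnoses(NULL, mk_ckd(3L, end_h = -200), enc1)
  expect_equal(ds2$detection_date, as.Date(ts0(0), tz = "UTC"))
})

test_that("findings from another patient raise a linkage error", {
  expect_error(combine_diagnoses(mk_aki(patient_id = "P99"), NULL, enc1),
               class = "renalrules_linkage_error")
})

test_that("ICD emission is a pure stage lookup that never mixes unspecified with specific", {
  m <- default_icd_map()
  expect_identical(map_icd(combine_diagnoses(mk_aki(3L), NULL, enc1), m), "N17.93")
  expect_identical(map_icd(combine_diagnoses(NULL, mk_ckd(4L), enc1), m), "N18.4")
  expect_identical(map_icd(combine_diagnoses(mk_aki(1L), mk_ckd(5L), enc1), m),
                   c("N17.91", "N18.5"))
  unspec <- mk_ckd(3L); unspec$stage <- "unspecified"; unspec$evidence <- "transplant"
  expect_identical(map_icd(combine_diagnoses(NULL, unspec, enc1), m), "N18.9")
  expect_identical(map_icd(combine_diagnoses(NULL, NULL, enc1), m), character(0))
  # same inputs, same codes; N19 never accompanies a specific code
  for (ds in list(combine_diagnoses(mk_aki(2L), mk_ckd(2L), enc1))) {
    c1 <- map_icd(ds, m); c2 <- map_icd(ds, m)
    expect_identical(c1, c2)
    expect_false(m$unspecified_any %in% c1)
  }
})

test_that("an incomplete catalog map is rejected", {
  m <- default_icd_map()
  m$ckd_stage_codes <- m$ckd_stage_codes[c("2", "3", "4")]
  expect_error(map_icd(combine_diagnoses(NULL, mk_ckd(5L), enc1), m),
               class = "renalrules_config_error")
  expect_error(icd_map("x", c(`1` = "bad code", `2` = "N17.92", `3` = "N17.93"),
                       c(`2` = "N18.2", `3` = "N18.3", `4` = "N18.4", `5` = "N18.5"),
                       "N18.9", "N19"),
               class = "renalrules_config_error")
})

test_that("the ICD map round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    catalog_id = "catalog-2018",
    aki_stage_codes = list(`1` = "N17.91", `2` = "N17.92", `3` = "N17.93"),
    ckd_stage_codes = list(`2` = "N18.2", `3` = "N18.3", `4` = "N18.4", `5` = "N18.5"),
    unspecified_chronic = "N18.9", unspecified_any = "N19"
  ), path)
  m <- read_icd_map(path)
  expect_identical(m$catalog_id, "catalog-2018")
  expect_identical(unname(m$aki_stage_codes[["2"]]), "N17.92")
})

test_that("validation transitions are single-shot and logged; rejection deletes the codes", {
  ds <- combine_diagnoses(mk_aki(2L), NULL, enc1, map = default_icd_map())
  acc <- apply_validation(ds, "accept")
  expect_identical(acc$validation_status, "validated")
  expect_identical(acc$icd_codes, "N17.92")

  rej <- apply_validation(ds, "reject", reason = "not documented")
  expect_identical(rej$validation_status, "rejected")
  expect_length(rej$icd_codes, 0)
  expect_equal(nrow(rej$mutations), 1)
  expect_identical(rej$mutations$from_codes, "N17.92")
  expect_identical(rej$mutations$to_codes, "")

  expect_error(apply_validation(acc, "reject"), class = "renalrules_state_error")
  expect_error(apply_validation(rej, "accept"), class = "renalrules_state_error")
})

test_that("the mutation log replays every state transition", {
  m <- default_icd_map()
  sets <- list(
    apply_validation(combine_diagnoses(mk_aki(1L), NULL, enc1, m), "accept"),
    apply_validation(combine_diagnoses(NULL, mk_ckd(3L),
                                       list(case_id = "C2", patient_id = "P1",
                                            admit_ts = ts0(0), discharge_ts = ts0(240)),
                                       m), "reject")
  )
  log <- mutation_log(sets)
  expect_equal(nrow(log), 2)
  # replaying: final codes equal the to_codes of each case's last entry
  for (ds in sets) {
    last <- log[log$case_id == ds$case_id, ]
    expect_identical(paste(ds$icd_codes, collapse = ";"),
                     last$to_codes[nrow(last)])
  }
})
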