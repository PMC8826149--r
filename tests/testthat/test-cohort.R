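write_fixture_cohort <- function(dir, labs_extra = NULL, drop_col = NULL,
                                 bad_unit = FALSE, orphan_case = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patients <- data.frame(
    patient_id = c("P1", "P2"),
    birth_date = c("1960-04-02", "1975-11-20"),
    sex = c("female", "male"),
    black_race = c(FALSE, FALSE),
    transplant_history = c(FALSE, TRUE)
  )
  encounters <- data.frame(
    case_id = "C1", patient_id = "P1",
    admit_ts = "2019-03-01T08:00:00Z", discharge_ts = "2019-03-10T16:00:00Z"
  )
  labs <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    case_id = c("C1", "C1", "C1", NA, NA),
    analyte = c("scr", "scr", "egfr", "scr", "scr"),
    value = c(88, 1.0, 75, 70, 72),
    unit = c("µmol/L", "mg/dL", "mL/min/1.73m²", "µmol/L", "µmol/L"),
    ts = c("2019-03-01T09:00:00Z", "2019-03-02T09:00:00Z",
           "2019-03-03T09:00:00Z", "2019-01-05T09:00:00Z",
           "2019-01-06T09:00:00Z"),
    setting = c("inpatient", "inpatient", "inpatient", "outpatient", "outpatient")
  )
  if (bad_unit) labs$unit[1] <- "mmol/L"
  if (orphan_case) labs$case_id[1] <- "C999"
  if (!is.null(labs_extra)) labs <- rbind(labs, labs_extra)
  if (!is.null(drop_col)) patients[[drop_col]] <- NULL
  utils::write.csv(patients, file.path(dir, "patients.csv"), row.names = FALSE, na = "")
  utils::write.csv(encounters, file.path(dir, "encounters.csv"), row.names = FALSE, na = "")
  utils::write.csv(labs, file.path(dir, "labs.csv"), row.names = FALSE, na = "")
  dir
}

test_that("well-formed files ingest with exact counts and creatinine normalised to µmol/L", {
  dir <- write_fixture_cohort(withr::local_tempdir())
  co <- read_cohort(file.path(dir, "patients.csv"), file.path(dir, "encounters.csv"),
                    file.path(dir, "labs.csv"))
  expect_s3_class(co, "kd_cohort")
  expect_equal(nrow(co$patients), 2)
  expect_equal(nrow(co$encounters), 1)
  expect_equal(nrow(co$labs), 5)
  # 1.0 mg/dL stored as 88.4 µmol/L
  scr <- co$labs[co$labs$analyte == "scr" & co$labs$patient_id == "P1", ]
  expect_true(all(scr$unit == "µmol/L"))
  expect_equal(sort(scr$value), c(88, 88.4))
})

test_that("ingest errors name the defect: missing column, orphan case, unknown unit", {
  dir <- write_fixture_cohort(withr::local_tempdir(), drop_col = "sex")
  expect_error(
    read_cohort(file.path(dir, "patients.csv"), file.path(dir, "encounters.csv"),
                file.path(dir, "labs.csv")),
    regexp = "sex", class = "renalrules_schema_error")

  dir <- write_fixture_cohort(withr::local_tempdir(), orphan_case = TRUE)
  expect_error(
    read_cohort(file.path(dir, "patients.csv"), file.path(dir, "encounters.csv"),
                file.path(dir, "labs.csv")),
    regexp = "C999", class = "renalrules_referential_error")

  dir <- write_fixture_cohort(withr::local_tempdir(), bad_unit = TRUE)
  expect_error(
    read_cohort(file.path(dir, "patients.csv"), file.path(dir, "encounters.csv"),
                file.path(dir, "labs.csv")),
    class = "renalrules_unit_error")
})

test_that("duplicate (patient, analyte, ts) rows keep the last occurrence and are accounted for", {
  dup <- data.frame(
    patient_id = "P1", case_id = "C1", analyte = "scr", value = 99,
    unit = "µmol/L", ts = "2019-03-01T09:00:00Z", setting = "inpatient"
  )
  dir <- write_fixture_cohort(withr::local_tempdir(), labs_extra = dup)
  co <- read_cohort(file.path(dir, "patients.csv"), file.path(dir, "encounters.csv"),
                    file.path(dir, "labs.csv"))
  # 6 rows in = 5 kept + 1 rejected with a reason; the later row (99) wins
  expect_equal(nrow(co$labs) + nrow(co$rejected), 6)
  expect_equal(nrow(co$rejected), 1)
  expect_match(co$rejected$reason, "duplicate")
  kept <- co$labs[co$labs$patient_id == "P1" &
                    co$labs$ts == parse_ts("2019-03-01T09:00:00Z") &
                    co$labs$analyte == "scr", ]
  expect_equal(kept$value, 99)
})

test_that("care setting is taken from the column and inferred from encounter overlap only when absent", {
  dir <- write_fixture_cohort(withr::local_tempdir())
  labs <- utils::read.csv(file.path(dir, "labs.csv"))
  labs$setting <- NULL
  utils::write.csv(labs, file.path(dir, "labs.csv"), row.names = FALSE, na = "")
  co <- read_cohort(file.path(dir, "patients.csv"), file.path(dir, "encounters.csv"),
                    file.path(dir, "labs.csv"))
  p1 <- co$labs[co$labs$patient_id == "P1", ]
  p2 <- co$labs[co$labs$patient_id == "P2", ]
  expect_true(all(p1$setting == "inpatient"))   # inside C1's stay
  expect_true(all(p2$setting == "outpatient"))  # no encounter for P2
})

test_that("a cohort round-trips through write_cohort/read_cohort field-exactly", {
  g <- generate_cohort(synth_config(n_patients = 8), seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, dir)
  co2 <- read_cohort(file.path(dir, "patients.csv"), file.path(dir, "encounters.csv"),
                     file.path(dir, "labs.csv"), file.path(dir, "reports.csv"))
  for (tab in c("patients", "encounters", "labs", "reports")) {
    expect_equal(as.data.frame(co2[[tab]]), as.data.frame(g$cohort[[tab]]),
                 tolerance = 1e-12, info = tab)
  }
})

test_that("findings tables round-trip through write_findings/read_findings", {
  g <- generate_cohort(synth_config(n_patients = 12), seed = 5)
  res <- run_pipeline(g$cohort)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_findings(res$final, path)
  back <- read_findings(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})
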