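#' @importFrom dplyr arrange mutate filter select left_join group_by ungroup
#'   summarise slice n row_number bind_rows distinct rename
NULL

PATIENT_COLS <- c("patient_id", "birth_date", "sex")
ENCOUNTER_COLS <- c("case_id", "patient_id", "admit_ts", "discharge_ts")
LAB_COLS <- c("patient_id", "analyte", "value", "unit", "ts")
REPORT_COLS <- c("case_id", "report_ts", "report_type", "text")

ANALYTES <- c("scr", "egfr", "urine_albumin", "urine_creatinine")
LEGAL_UNITS <- list(
  scr = c("µmol/L", "umol/L", "mg/dL"),
  egfr = c("mL/min/1.73m²", "mL/min/1.73m2", "ml/min/1.73m2"),
  urine_albumin = c("mg/L"),
  urine_creatinine = c("mmol/L", "g/L")
)

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_schema(sprintf("%s is missing column(s): %s", what,
                        paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read and validate a cohort from delimited files
#'
#' Ingests the three core tables (patients, encounters, laboratory
#' measurements) plus optional discharge reports, resolves all
#' cross-references, normalises serum creatinine to µmol/L, orders each
#' patient's series by time and labels each measurement's care setting.
#'
#' Validation is strict: a missing column raises a schema error naming
#' the column; a lab or report row whose `case_id`/`patient_id` does not
#' resolve raises a referential error listing the offending rows; an
#' unknown unit for an analyte raises a unit error. Duplicate
#' (patient, analyte, timestamp) rows keep the last occurrence; the
#' discarded rows are returned in the `rejected` element so that no row
#' is dropped silently.
#'
#' @param patients_path,encounters_path,labs_path CSV paths (UTF-8,
#'   header row) with columns
#'   `patient_id,birth_date,sex,black_race,transplant_history`,
#'   `case_id,patient_id,admit_ts,discharge_ts` and
#'   `patient_id,case_id,analyte,value,unit,ts,setting` respectively.
#' @param reports_path Optional CSV of discharge reports
#'   (`case_id,report_ts,report_type,text`).
#' @return An object of class `kd_cohort`: a list with tibbles
#'   `patients`, `encounters`, `labs`, `reports` and `rejected`.
#' @export
read_cohort <- function(patients_path, encounters_path, labs_path,
                        reports_path = NULL) {
  for (p in c(patients_path, encounters_path, labs_path)) {
    if (!file.exists(p)) stop_schema(paste0("input file not found: ", p))
  }
  patients <- readr::read_csv(patients_path, show_col_types = FALSE,
                              col_types = readr::cols(.default = "c"))
  encounters <- readr::read_csv(encounters_path, show_col_types = FALSE,
                                col_types = readr::cols(.default = "c"))
  labs <- readr::read_csv(labs_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  reports <- if (!is.null(reports_path)) {
    if (!file.exists(reports_path)) stop_schema(paste0("input file not found: ", reports_path))
    readr::read_csv(reports_path, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    tibble(case_id = character(), report_ts = parse_ts(character()),
           report_type = character(), text = character())
  }
  as_kd_cohort(patients, encounters, labs, reports)
}

#' Assemble a validated cohort from in-memory tables
#'
#' Same validation and normalisation as [read_cohort()], starting from
#' data frames instead of files (the synthetic generator uses this path).
#'
#' @param patients,encounters,labs,reports Data frames with the columns
#'   documented in [read_cohort()].
#' @return A `kd_cohort` object.
#' @export
as_kd_cohort <- function(patients, encounters, labs, reports = NULL) {
  check_columns(patients, PATIENT_COLS, "patients table")
  check_columns(encounters, ENCOUNTER_COLS, "encounters table")
  check_columns(labs, LAB_COLS, "labs table")

  patients <- as_tibble(patients) |>
    mutate(
      patient_id = as.character(.data$patient_id),
      birth_date = as.Date(.data$birth_date),
      sex = as.character(.data$sex),
      black_race = parse_flag(if ("black_race" %in% names(patients)) patients$black_race else FALSE),
      transplant_history = parse_flag(if ("transplant_history" %in% names(patients)) patients$transplant_history else FALSE)
    )
  if (anyDuplicated(patients$patient_id)) {
    stop_ref("duplicate patient_id in patients table")
  }
  bad_sex <- setdiff(unique(patients$sex), c("female", "male"))
  if (length(bad_sex)) stop_schema(paste0("unknown sex value(s): ", paste(bad_sex, collapse = ", ")))

  encounters <- as_tibble(encounters) |>
    mutate(
      case_id = as.character(.data$case_id),
      patient_id = as.character(.data$patient_id),
      admit_ts = parse_ts(.data$admit_ts),
      discharge_ts = parse_ts(.data$discharge_ts)
    )
  if (anyDuplicated(encounters$case_id)) stop_ref("duplicate case_id in encounters table")
  if (any(encounters$admit_ts >= encounters$discharge_ts)) {
    bad <- encounters$case_id[encounters$admit_ts >= encounters$discharge_ts]
    stop_ref(paste0("admit_ts not before discharge_ts for case(s): ",
                    paste(bad, collapse = ", ")))
  }
  orphan_enc <- setdiff(encounters$patient_id, patients$patient_id)
  if (length(orphan_enc)) {
    stop_ref(paste0("encounter patient_id not in patients: ",
                    paste(orphan_enc, collapse = ", ")))
  }

  labs <- as_tibble(labs) |>
    mutate(
      patient_id = as.character(.data$patient_id),
      case_id = if ("case_id" %in% names(labs)) as.character(labs$case_id) else NA_character_,
      analyte = as.character(.data$analyte),
      value = as.numeric(.data$value),
      unit = as.character(.data$unit),
      ts = parse_ts(.data$ts),
      setting = if ("setting" %in% names(labs)) as.character(labs$setting) else NA_character_
    )
  bad_analyte <- setdiff(unique(labs$analyte), ANALYTES)
  if (length(bad_analyte)) {
    stop_schema(paste0("unknown analyte(s): ", paste(bad_analyte, collapse = ", ")))
  }
  if (any(labs$value < 0, na.rm = TRUE)) stop_domain("negative lab value(s)")
  for (an in unique(labs$analyte)) {
    bad_unit <- setdiff(unique(labs$unit[labs$analyte == an]), LEGAL_UNITS[[an]])
    if (length(bad_unit)) {
      stop_unit(sprintf("unit(s) %s not legal for analyte %s",
                        paste(bad_unit, collapse = ", "), an))
    }
  }
  orphan_pid <- setdiff(labs$patient_id, patients$patient_id)
  if (length(orphan_pid)) {
    stop_ref(paste0("lab patient_id not in patients: ", paste(orphan_pid, collapse = ", ")))
  }
  orphan_case <- setdiff(labs$case_id[!is.na(labs$case_id) & labs$case_id != ""],
                         encounters$case_id)
  if (length(orphan_case)) {
    rows <- which(labs$case_id %in% orphan_case)
    stop_ref(sprintf("lab case_id not in encounters (rows %s): %s",
                     paste(utils::head(rows, 10), collapse = ","),
                     paste(orphan_case, collapse = ", ")))
  }

  # serum creatinine canonical unit is µmol/L
  is_mgdl <- labs$analyte == "scr" & labs$unit == "mg/dL"
  labs$value[is_mgdl] <- creatinine_mgdl_to_umol(labs$value[is_mgdl])
  labs$unit[labs$analyte == "scr"] <- "µmol/L"

  # care setting from the input column; infer from encounter overlap if absent
  need_setting <- is.na(labs$setting) | labs$setting == ""
  if (any(need_setting)) {
    labs$setting[need_setting] <- infer_setting(labs[need_setting, ], encounters)
  }
  bad_setting <- setdiff(unique(labs$setting), c("inpatient", "outpatient"))
  if (length(bad_setting)) {
    stop_schema(paste0("unknown setting value(s): ", paste(bad_setting, collapse = ", ")))
  }

  # duplicates on (patient, analyte, ts): keep the last occurrence, report the rest
  labs <- labs |> mutate(.row = row_number())
  dup_key <- paste(labs$patient_id, labs$analyte, format(labs$ts, "%Y-%m-%dT%H:%M:%OS3"))
  keep_last <- !duplicated(dup_key, fromLast = TRUE)
  rejected <- labs[!keep_last, ] |>
    mutate(reason = "duplicate (patient, analyte, ts); superseded by later row") |>
    select(-".row")
  labs <- labs[keep_last, ] |>
    arrange(.data$patient_id, .data$ts, .data$analyte) |>
    select(-".row")

  # birth precedes every measurement
  labs_bd <- left_join(labs, select(patients, "patient_id", "birth_date"),
                       by = "patient_id")
  if (any(as.Date(labs_bd$ts) < labs_bd$birth_date)) {
    stop_ref("measurement timestamp precedes patient birth_date")
  }

  if (!is.null(reports) && nrow(reports)) {
    check_columns(reports, REPORT_COLS, "reports table")
    reports <- as_tibble(reports) |>
      mutate(case_id = as.character(.data$case_id),
             report_ts = parse_ts(.data$report_ts),
             report_type = as.character(.data$report_type),
             text = as.character(.data$text))
    orphan_rep <- setdiff(reports$case_id, encounters$case_id)
    if (length(orphan_rep)) {
      stop_ref(paste0("report case_id not in encounters: ",
                      paste(orphan_rep, collapse = ", ")))
    }
  } else {
    reports <- tibble(case_id = character(), report_ts = parse_ts(character()),
                      report_type = character(), text = character())
  }

  structure(
    list(patients = patients, encounters = encounters, labs = labs,
         reports = reports, rejected = rejected),
    class = "kd_cohort"
  )
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

infer_setting <- function(lab_rows, encounters) {
  vapply(seq_len(nrow(lab_rows)), function(i) {
    enc <- encounters[encounters$patient_id == lab_rows$patient_id[i], ]
    inside <- nrow(enc) > 0 &&
      any(enc$admit_ts <= lab_rows$ts[i] & lab_rows$ts[i] <= enc$discharge_ts)
    if (inside) "inpatient" else "outpatient"
  }, character(1))
}

#' @export
print.kd_cohort <- function(x, ...) {
  cat(sprintf(
    "<kd_cohort> %d patients, %d encounters, %d lab measurements, %d reports\n",
    nrow(x$patients), nrow(x$encounters), nrow(x$labs), nrow(x$reports)))
  if (nrow(x$rejected)) {
    cat(sprintf("  %d rejected lab row(s) (see $rejected)\n", nrow(x$rejected)))
  }
  invisible(x)
}

#' Write cohort tables to a directory of CSV files
#'
#' Inverse of [read_cohort()]: emits `patients.csv`, `encounters.csv`,
#' `labs.csv` and, when reports exist, `reports.csv`. Timestamps are
#' serialised as ISO-8601 UTC so a round trip through
#' [read_cohort()] is field-exact after unit normalisation.
#'
#' @param cohort A `kd_cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "kd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "")
  enc <- cohort$encounters |>
    mutate(admit_ts = fmt(.data$admit_ts), discharge_ts = fmt(.data$discharge_ts))
  readr::write_csv(enc, file.path(dir, "encounters.csv"), na = "")
  labs <- cohort$labs |> mutate(ts = fmt(.data$ts))
  readr::write_csv(labs, file.path(dir, "labs.csv"), na = "")
  if (nrow(cohort$reports)) {
    rep <- cohort$reports |> mutate(report_ts = fmt(.data$report_ts))
    readr::write_csv(rep, file.path(dir, "reports.csv"), na = "")
  }
  invisible(dir)
}

#' Serialise diagnosis sets to a findings table / CSV
#'
#' One row per case with the staged findings, the acute-on-chronic flag,
#' the emitted ICD codes (joined with `;`) and the detection date.
#' [read_findings()] restores the table without loss.
#'
#' @param diagnoses List of `diagnosis_set` objects (see
#'   [combine_diagnoses()]).
#' @param path Output CSV path.
#' @return The findings tibble, invisibly for `write_findings()`.
#' @export
write_findings <- function(diagnoses, path) {
  tab <- findings_table(diagnoses)
  out <- tab |>
    mutate(detection_date = format(.data$detection_date, "%Y-%m-%d"))
  readr::write_csv(out, path, na = "")
  invisible(tab)
}

#' @rdname write_findings
#' @export
findings_table <- function(diagnoses) {
  rows <- lapply(diagnoses, function(ds) {
    stopifnot(inherits(ds, "diagnosis_set"))
    tibble(
      case_id = ds$case_id,
      patient_id = ds$patient_id,
      aki_stage = if (is.null(ds$aki)) NA_integer_ else as.integer(ds$aki$stage),
      aki_criterion = if (is.null(ds$aki)) NA_character_ else ds$aki$criterion,
      ckd_stage = if (is.null(ds$ckd)) NA_character_ else as.character(ds$ckd$stage),
      acr_category = if (is.null(ds$ckd) || is.null(ds$ckd$acr)) NA_character_
                     else ds$ckd$acr$category,
      acute_on_chronic = ds$acute_on_chronic,
      icd_codes = paste(ds$icd_codes, collapse = ";"),
      detection_date = ds$detection_date
    )
  })
  bind_rows(rows)
}

#' @rdname write_findings
#' @export
read_findings <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    case_id = "c", patient_id = "c", aki_stage = "i",
                    aki_criterion = "c", ckd_stage = "c", acr_category = "c",
                    acute_on_chronic = "l", icd_codes = "c",
                    detection_date = readr::col_date()
                  )) |>
    mutate(icd_codes = ifelse(is.na(.data$icd_codes), "", .data$icd_codes))
}
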