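ICD_CODE_PATTERN <- "^[A-Z][0-9]+(\\.[0-9]+)?$"

#' ICD code catalog map
#'
#' The stage-to-code map is data, not logic: catalog-year variants are
#' alternative configuration files. The shipped default assigns AKI
#' stages 1/2/3 to N17.91/N17.92/N17.93, CKD stages 2-5 to N18.2-N18.5,
#' unspecified chronic kidney disease to N18.9 and unspecified kidney
#' failure to N19.
#'
#' @param catalog_id Free-text label of the catalog the map encodes.
#' @param aki_stage_codes Named character vector, names "1","2","3".
#' @param ckd_stage_codes Named character vector, names "2".."5".
#' @param unspecified_chronic,unspecified_any Single code strings.
#' @return Validated list of class `icd_map`.
#' @export
icd_map <- function(catalog_id, aki_stage_codes, ckd_stage_codes,
                    unspecified_chronic, unspecified_any) {
  m <- structure(
    list(catalog_id = catalog_id,
         aki_stage_codes = aki_stage_codes,
         ckd_stage_codes = ckd_stage_codes,
         unspecified_chronic = unspecified_chronic,
         unspecified_any = unspecified_any),
    class = "icd_map"
  )
  validate_icd_map(m)
}

validate_icd_map <- function(m) {
  if (!all(c("1", "2", "3") %in% names(m$aki_stage_codes))) {
    stop_config("icd_map must code every AKI stage 1-3")
  }
  if (!all(c("2", "3", "4", "5") %in% names(m$ckd_stage_codes))) {
    stop_config("icd_map must code every CKD stage 2-5")
  }
  codes <- c(m$aki_stage_codes, m$ckd_stage_codes,
             m$unspecified_chronic, m$unspecified_any)
  bad <- codes[!grepl(ICD_CODE_PATTERN, codes)]
  if (length(bad)) {
    stop_config(paste0("malformed ICD code(s): ", paste(bad, collapse = ", ")))
  }
  m
}

#' @rdname icd_map
#' @export
default_icd_map <- function() {
  icd_map(
    catalog_id = "default-n17-n18",
    aki_stage_codes = c(`1` = "N17.91", `2` = "N17.92", `3` = "N17.93"),
    ckd_stage_codes = c(`2` = "N18.2", `3` = "N18.3", `4` = "N18.4", `5` = "N18.5"),
    unspecified_chronic = "N18.9",
    unspecified_any = "N19"
  )
}

#' @rdname icd_map
#' @param path Path to a YAML file with fields `catalog_id`,
#'   `aki_stage_codes`, `ckd_stage_codes`, `unspecified_chronic`,
#'   `unspecified_any`.
#' @export
read_icd_map <- function(path) {
  if (!file.exists(path)) stop_config(paste0("icd map file not found: ", path))
  y <- yaml::read_yaml(path)
  icd_map(
    catalog_id = y$catalog_id %||% "unnamed",
    aki_stage_codes = unlist(y$aki_stage_codes),
    ckd_stage_codes = unlist(y$ckd_stage_codes),
    unspecified_chronic = y$unspecified_chronic,
    unspecified_any = y$unspecified_any
  )
}

#' @export
print.icd_map <- function(x, ...) {
  cat(sprintf("<icd_map> %s: AKI %s; CKD %s; unspecified %s/%s\n",
              x$catalog_id,
              paste(x$aki_stage_codes, collapse = "/"),
              paste(x$ckd_stage_codes, collapse = "/"),
              x$unspecified_chronic, x$unspecified_any))
  invisible(x)
}

#' Combine per-case findings into a diagnosis set
#'
#' Joins the optional AKI and CKD findings of one inpatient case,
#' raises the acute-on-chronic flag exactly when both are present, and
#' anchors the detection date to the date of the latest contributing
#' measurement, clamped into the admission-discharge window so the code
#' attaches to the inpatient case.
#'
#' @param aki Optional [classify_aki()] finding.
#' @param ckd Optional [classify_ckd()] finding.
#' @param encounter One-row encounter with `case_id`, `patient_id`,
#'   `admit_ts`, `discharge_ts`.
#' @param map Optional [icd_map()]; when supplied the ICD codes are
#'   emitted immediately via [map_icd()].
#' @return A list of class `diagnosis_set` with fields `case_id`,
#'   `patient_id`, `aki`, `ckd`, `acute_on_chronic`, `icd_codes`,
#'   `detection_date`, `validation_status` (`"generated"`) and a
#'   `mutations` log tibble.
#' @export
combine_diagnoses <- function(aki, ckd, encounter, map = NULL) {
  for (f in list(aki, ckd)) {
    if (!is.null(f) && !is.null(f$patient_id) &&
        f$patient_id != encounter$patient_id) {
      abort("finding belongs to a different patient than the case",
            class = "renalrules_linkage_error")
    }
  }
  admit <- parse_ts(encounter$admit_ts)
  discharge <- parse_ts(encounter$discharge_ts)
  contrib <- Filter(Negate(is.null), list(
    if (!is.null(aki)) aki$second_ts,
    if (!is.null(ckd)) ckd$window_end_ts,
    if (!is.null(ckd) && !is.null(ckd$acr)) ckd$acr$albumin_ts
  ))
  detection <- if (length(contrib)) do.call(max, contrib) else discharge
  detection <- min(max(detection, admit), discharge)
  ds <- structure(
    list(case_id = encounter$case_id, patient_id = encounter$patient_id,
         aki = aki, ckd = ckd,
         acute_on_chronic = !is.null(aki) && !is.null(ckd),
         icd_codes = character(0),
         detection_date = as.Date(detection, tz = "UTC"),
         validation_status = "generated",
         mutations = empty_mutation_log()),
    class = "diagnosis_set"
  )
  if (!is.null(map)) ds$icd_codes <- map_icd(ds, map)
  ds
}

#' Emit ICD codes for a diagnosis set
#'
#' Pure table lookup: the AKI stage and the CKD stage each map to their
#' catalog code; unspecified-stage CKD maps to the unspecified chronic
#' code; both families are emitted for acute-on-chronic cases; a case
#' with no finding gets no code. The catch-all unspecified code is never
#' emitted when a specific finding exists.
#'
#' @param ds A `diagnosis_set`.
#' @param map An [icd_map()].
#' @return Character vector of ICD codes (possibly empty).
#' @examples
#' m <- default_icd_map()
#' m$aki_stage_codes[["3"]] # "N17.93"
#' @export
map_icd <- function(ds, map = default_icd_map()) {
  validate_icd_map(map)
  codes <- character(0)
  if (!is.null(ds$aki)) {
    key <- as.character(ds$aki$stage)
    if (!key %in% names(map$aki_stage_codes)) {
      stop_config(paste0("AKI stage ", key, " missing from icd_map"))
    }
    codes <- c(codes, unname(map$aki_stage_codes[key]))
  }
  if (!is.null(ds$ckd)) {
    if (identical(ds$ckd$stage, "unspecified")) {
      codes <- c(codes, map$unspecified_chronic)
    } else {
      key <- as.character(ds$ckd$stage)
      if (!key %in% names(map$ckd_stage_codes)) {
        stop_config(paste0("CKD stage ", key, " missing from icd_map"))
      }
      codes <- c(codes, unname(map$ckd_stage_codes[key]))
    }
  }
  codes
}

empty_mutation_log <- function() {
  tibble(case_id = character(0), ts = as.Date(character(0)),
         from_codes = character(0), to_codes = character(0),
         reason = character(0))
}

#' Apply a clinician validation decision to a diagnosis set
#'
#' Automatically generated diagnoses are validated retrospectively;
#' accepting retains the codes, rejecting deletes them. Every
#' transition is appended to the set's mutation log so the full code
#' history can be replayed. A set can be validated only once.
#'
#' @param ds A `diagnosis_set` in state `"generated"`.
#' @param decision `"accept"` or `"reject"`.
#' @param reason Free-text reason recorded in the log.
#' @return The updated `diagnosis_set`.
#' @export
apply_validation <- function(ds, decision, reason = "") {
  decision <- match.arg(decision, c("accept", "reject"))
  if (!identical(ds$validation_status, "generated")) {
    stop_state(paste0("diagnosis set already ", ds$validation_status,
                      "; cannot validate twice"))
  }
  from <- paste(ds$icd_codes, collapse = ";")
  if (decision == "accept") {
    ds$validation_status <- "validated"
  } else {
    ds$validation_status <- "rejected"
    ds$icd_codes <- character(0)
  }
  ds$mutations <- bind_rows(ds$mutations, tibble(
    case_id = ds$case_id, ts = ds$detection_date,
    from_codes = from, to_codes = paste(ds$icd_codes, collapse = ";"),
    reason = if (nzchar(reason)) reason else decision
  ))
  ds
}

#' Collect the mutation logs of many diagnosis sets
#'
#' @param diagnoses List of `diagnosis_set` objects.
#' @return Append-only tibble `case_id,ts,from_codes,to_codes,reason`.
#' @export
mutation_log <- function(diagnoses) {
  logs <- lapply(diagnoses, `[[`, "mutations")
  if (!length(logs)) return(empty_mutation_log())
  bind_rows(logs)
}

#' @export
print.diagnosis_set <- function(x, ...) {
  cat(sprintf("<diagnosis_set> case %s: %s%s%s [%s] codes: %s\n",
              x$case_id,
              if (!is.null(x$aki)) paste0("AKI ", x$aki$stage) else "no AKI",
              if (x$acute_on_chronic) " + " else " / ",
              if (!is.null(x$ckd)) paste0("CKD ", x$ckd$stage) else "no CKD",
              x$validation_status,
              if (length(x$icd_codes)) paste(x$icd_codes, collapse = ";") else "none"))
  invisible(x)
}
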