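#' Pair urine albumin with urine creatinine and compute ACR results
#'
#' Each urinary albumin measurement is paired with the closest-in-time
#' urinary creatinine of the same patient within 30 days; pairs from one
#' sample (identical timestamps) are preferred automatically because
#' their interval is zero.
#'
#' @param labs Lab tibble of one patient (normalised units, sorted).
#' @return List of [compute_acr()] results (possibly empty).
#' @export
acr_results_for_patient <- function(labs) {
  alb <- labs[labs$analyte == "urine_albumin", ]
  cre <- labs[labs$analyte == "urine_creatinine", ]
  if (!nrow(alb) || !nrow(cre)) return(list())
  out <- list()
  for (i in seq_len(nrow(alb))) {
    gaps <- abs(hours_between(cre$ts, alb$ts[i]))
    j <- which.min(gaps)
    if (gaps[j] > 720) next
    out[[length(out) + 1]] <- compute_acr(
      list(value = alb$value[i], ts = alb$ts[i]),
      list(value = cre$value[j], unit = cre$unit[j], ts = cre$ts[j])
    )
  }
  out
}

#' Run the full diagnostic pipeline over a cohort
#'
#' Ingest, AKI and CKD staging per inpatient case, acute-on-chronic
#' combination, ICD code emission, optional clinician validation, text
#' audit of discharge reports, and the prevalence/conversion tables.
#' Deterministic: identical inputs and configuration produce identical
#' outputs (run time appears only in the manifest).
#'
#' @param cohort A `kd_cohort` from [read_cohort()] or
#'   [generate_cohort()].
#' @param out_dir Optional directory; when given, `findings.csv`,
#'   per-term hit CSVs, `case_audit.csv`, `prevalence.csv`,
#'   `conversion.csv`, `mutations.log` and `run_manifest.yaml` are
#'   written there.
#' @param map [icd_map()] used for code emission.
#' @param terms Term configuration for the text audit.
#' @param config Engine constants from [kd_config()].
#' @param validation Optional tibble `case_id, decision` (accept/reject)
#'   applied to the generated diagnoses.
#' @param period_assignment Optional tibble `case_id, period_label` for
#'   the reporting tables (defaults to discharge year).
#' @return List with `diagnoses` (generated), `final` (after
#'   validation), `findings` (tibble), `hits`, `case_audit`,
#'   `prevalence`, `conversion` and `mutations`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, map = default_icd_map(),
                         terms = default_terms(), config = kd_config(),
                         validation = NULL, period_assignment = NULL) {
  stopifnot(inherits(cohort, "kd_cohort"))
  validate_icd_map(map)
  labs_by_patient <- split(cohort$labs, cohort$labs$patient_id)
  patients_by_id <- split(cohort$patients, cohort$patients$patient_id)

  diagnoses <- vector("list", nrow(cohort$encounters))
  for (k in seq_len(nrow(cohort$encounters))) {
    enc <- cohort$encounters[k, ]
    plabs <- labs_by_patient[[enc$patient_id]]
    patient <- patients_by_id[[enc$patient_id]][1, ]
    scr <- if (is.null(plabs)) NULL else plabs[plabs$analyte == "scr", c("value", "ts")]
    egfr <- if (is.null(plabs)) NULL else plabs[plabs$analyte == "egfr", c("value", "ts")]
    aki <- if (!is.null(scr) && nrow(scr)) {
      classify_aki(enc, scr, baseline = NULL, config = config)
    } else NULL
    acrs <- if (is.null(plabs)) list() else acr_results_for_patient(plabs)
    ckd <- classify_ckd(patient, egfr, acrs, index_date = enc$discharge_ts,
                        config = config)
    diagnoses[[k]] <- combine_diagnoses(aki, ckd, enc, map = map)
  }

  final <- diagnoses
  if (!is.null(validation) && nrow(validation)) {
    idx <- stats::setNames(seq_along(final),
                           vapply(final, `[[`, character(1), "case_id"))
    for (r in seq_len(nrow(validation))) {
      ci <- validation$case_id[r]
      if (!ci %in% names(idx)) stop_config(paste0("validation for unknown case ", ci))
      final[[idx[[ci]]]] <- apply_validation(final[[idx[[ci]]]],
                                             validation$decision[r])
    }
  }

  findings <- findings_table(final)
  hits <- if (nrow(cohort$reports)) {
    scan_reports(cohort$reports, terms, known_cases = cohort$encounters$case_id)
  } else {
    list()
  }
  case_audit <- if (length(hits)) aggregate_cases(hits, final) else NULL
  prevalence <- prevalence_table(cohort, final, period_assignment)
  conversion <- conversion_table(diagnoses, final, period_assignment, map)
  mutations <- mutation_log(final)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_findings(final, file.path(out_dir, "findings.csv"))
    for (term in names(hits)) {
      readr::write_csv(hits[[term]],
                       file.path(out_dir, paste0("hits_", term_column(term), ".csv")))
    }
    if (!is.null(case_audit)) {
      readr::write_csv(case_audit, file.path(out_dir, "case_audit.csv"))
    }
    readr::write_csv(prevalence, file.path(out_dir, "prevalence.csv"))
    readr::write_csv(conversion, file.path(out_dir, "conversion.csv"))
    readr::write_csv(mutations, file.path(out_dir, "mutations.log"))
    manifest <- list(
      package = "renalrules",
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      config = config[setdiff(names(config), "ckd.thresholds")],
      ckd_thresholds = as.list(config$ckd.thresholds),
      icd_catalog = map$catalog_id,
      config_hash = rlang::hash(list(config, map, terms)),
      cases_in = nrow(cohort$encounters),
      cases_with_findings = sum(vapply(final, function(d) length(d$icd_codes) > 0,
                                       logical(1)))
    )
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }

  list(diagnoses = diagnoses, final = final, findings = findings,
       hits = hits, case_audit = case_audit, prevalence = prevalence,
       conversion = conversion, mutations = mutations)
}
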