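#' Percentage with two decimals, half-up
#'
#' The arithmetic behind every printed percentage of the evaluation
#' tables: `100 * n / N` rounded half-up at two decimals.
#'
#' @param n Numerator count, `0 <= n <= N`.
#' @param N Denominator count, positive.
#' @return Percentage rounded to two decimals.
#' @examples
#' proportion(416, 9501)  # 4.38
#' proportion(2167, 4362) # 49.68
#' @export
proportion <- function(n, N) {
  if (any(N <= 0)) {
    abort("proportion undefined for non-positive denominator",
          class = "renalrules_undefined_proportion_error")
  }
  if (any(n < 0) || any(n > N)) stop_domain("numerator must lie in [0, N]")
  round_half_up(100 * n / N, 2)
}

#' Prevalence of reduced eGFR and of coded kidney disease per period
#'
#' For each reporting period: the number of inpatient cases, cases with
#' any eGFR measurement, cases with any eGFR below 60 mL/min/1.73 m²,
#' cases carrying any kidney-disease ICD code (N17-/N18-/N19- families),
#' and coded cases among those with reduced eGFR, together with their
#' percentages (of all inpatient cases, except the last, which is the
#' share of coded cases among the reduced-eGFR cases).
#'
#' @param cohort A `kd_cohort`.
#' @param diagnoses List of `diagnosis_set` objects (codes as currently
#'   held, i.e. after any validation).
#' @param period_assignment Optional tibble `case_id, period_label`
#'   assigning every case to exactly one period; defaults to the
#'   discharge year.
#' @return Tibble with one `PrevalenceRow` per period.
#' @export
prevalence_table <- function(cohort, diagnoses, period_assignment = NULL) {
  enc <- cohort$encounters
  if (is.null(period_assignment)) {
    period_assignment <- tibble(
      case_id = enc$case_id,
      period_label = format(enc$discharge_ts, "%Y")
    )
  }
  if (anyDuplicated(period_assignment$case_id)) {
    stop_config("overlapping period assignment: a case maps to several periods")
  }
  unassigned <- setdiff(enc$case_id, period_assignment$case_id)
  if (length(unassigned)) {
    stop_config(paste0("case(s) without period assignment: ",
                       paste(utils::head(unassigned, 5), collapse = ", ")))
  }

  egfr <- cohort$labs |> filter(.data$analyte == "egfr", !is.na(.data$case_id))
  cases_with_egfr <- unique(egfr$case_id)
  cases_egfr_lt60 <- unique(egfr$case_id[egfr$value < 60])
  coded <- vapply(diagnoses, function(ds) {
    any(startsWith(ds$icd_codes, "N17") | startsWith(ds$icd_codes, "N18") |
          startsWith(ds$icd_codes, "N19"))
  }, logical(1))
  cases_coded <- vapply(diagnoses, `[[`, character(1), "case_id")[coded]

  enc |>
    left_join(period_assignment, by = "case_id") |>
    group_by(.data$period_label) |>
    summarise(
      n_inpatient_cases = n(),
      n_with_egfr = sum(.data$case_id %in% cases_with_egfr),
      n_egfr_lt60 = sum(.data$case_id %in% cases_egfr_lt60),
      n_any_kd_coded = sum(.data$case_id %in% cases_coded),
      n_kd_coded_and_egfr_lt60 = sum(.data$case_id %in% cases_coded &
                                       .data$case_id %in% cases_egfr_lt60),
      .groups = "drop"
    ) |>
    mutate(
      pct_with_egfr = proportion(.data$n_with_egfr, .data$n_inpatient_cases),
      pct_egfr_lt60 = proportion(.data$n_egfr_lt60, .data$n_inpatient_cases),
      pct_any_kd_coded = proportion(.data$n_any_kd_coded, .data$n_inpatient_cases),
      pct_kd_coded_of_egfr_lt60 = ifelse(
        .data$n_egfr_lt60 > 0,
        proportion(.data$n_kd_coded_and_egfr_lt60, pmax(.data$n_egfr_lt60, 1)),
        NA_real_
      )
    ) |>
    arrange(.data$period_label)
}

#' Conversion of unspecified N19 codes under manual validation
#'
#' For every case whose generated codes include the unspecified code,
#' the final state is classified into conversions to the acute family
#' (N17-), the chronic family (N18-), codes left unspecified (N19), or
#' full rejection; the remainder `n19_generated - (to_n17 + to_n18 +
#' still_n19)` is the rejected count when the three outcome families
#' are disjoint. Cases converting to both families are counted once per
#' family and additionally reported in `n_combined` so the columns stay
#' auditable.
#'
#' @param generated List of `diagnosis_set` objects as generated by the
#'   engine (before validation/recoding).
#' @param final List of `diagnosis_set` objects holding the final codes
#'   for the same cases.
#' @param period_assignment Optional tibble `case_id, period_label`;
#'   defaults to a single row labelled `"all"`.
#' @param map The [icd_map()] defining the unspecified code.
#' @return Tibble with one `ConversionRow` per period: counts,
#'   `n_combined`, `rejected` and half-up percentages of
#'   `n19_generated`.
#' @export
conversion_table <- function(generated, final, period_assignment = NULL,
                             map = default_icd_map()) {
  gen_ids <- vapply(generated, `[[`, character(1), "case_id")
  fin_ids <- vapply(final, `[[`, character(1), "case_id")
  if (!setequal(gen_ids, fin_ids)) {
    stop_config("generated and final diagnosis sets must share case_ids")
  }
  fin_by_id <- stats::setNames(final, fin_ids)
  n19_cases <- gen_ids[vapply(generated, function(ds) {
    map$unspecified_any %in% ds$icd_codes
  }, logical(1))]

  if (is.null(period_assignment)) {
    period_assignment <- tibble(case_id = gen_ids, period_label = "all")
  }
  per <- stats::setNames(period_assignment$period_label, period_assignment$case_id)

  rows <- list()
  for (label in unique(period_assignment$period_label)) {
    ids <- n19_cases[per[n19_cases] == label]
    codes <- lapply(fin_by_id[ids], `[[`, "icd_codes")
    has17 <- vapply(codes, function(cc) any(startsWith(cc, "N17")), logical(1))
    has18 <- vapply(codes, function(cc) any(startsWith(cc, "N18")), logical(1))
    has19 <- vapply(codes, function(cc) map$unspecified_any %in% cc, logical(1))
    n <- length(ids)
    to17 <- sum(has17); to18 <- sum(has18)
    still <- sum(has19 & !has17 & !has18)
    rejected <- sum(!has17 & !has18 & !has19)
    rows[[length(rows) + 1]] <- tibble(
      period_label = label,
      n19_generated = n,
      to_n17 = to17, to_n18 = to18, still_n19 = still,
      n_combined = sum(has17 & has18), rejected = rejected,
      pct_to_n17 = if (n > 0) proportion(to17, n) else NA_real_,
      pct_to_n18 = if (n > 0) proportion(to18, n) else NA_real_,
      pct_still_n19 = if (n > 0) proportion(still, n) else NA_real_
    )
  }
  bind_rows(rows) |> arrange(.data$period_label)
}
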