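#' Enumerate chronicity windows in an eGFR series
#'
#' All ordered timestamp pairs spanning strictly more than 91 days
#' (2184 hours); each window carries every measurement inside its
#' closed interval, together with the min/mean/max eGFR, which are
#' retained for audit even though only the maximum participates in
#' staging.
#'
#' @param values Numeric eGFR values (mL/min/1.73 m²).
#' @param ts POSIXct timestamps matching `values`.
#' @param config Engine constants from [kd_config()].
#' @return Tibble with `start_ts`, `end_ts`, `span_hours`, `n_values`,
#'   `min_egfr`, `mean_egfr`, `max_egfr` and a list-column `values`.
#' @export
chronic_windows <- function(values, ts, config = kd_config()) {
  n <- length(values)
  stopifnot(length(ts) == n)
  empty <- tibble(start_ts = parse_ts(character(0)),
                  end_ts = parse_ts(character(0)),
                  span_hours = numeric(0), n_values = integer(0),
                  min_egfr = numeric(0), mean_egfr = numeric(0),
                  max_egfr = numeric(0), values = list())
  if (n < 2) return(empty)
  ord <- order(ts)
  values <- values[ord]; ts <- ts[ord]
  min_span <- config$ckd.chronicity_days * HOURS_PER_DAY
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      span <- hours_between(ts[i], ts[j])
      if (span <= min_span) next
      inside <- values[ts >= ts[i] & ts <= ts[j]]
      rows[[length(rows) + 1]] <- tibble(
        start_ts = ts[i], end_ts = ts[j], span_hours = span,
        n_values = length(inside), min_egfr = min(inside),
        mean_egfr = mean(inside), max_egfr = max(inside),
        values = list(inside)
      )
    }
  }
  if (!length(rows)) return(empty)
  bind_rows(rows)
}

#' Stage a chronicity window by its eGFR values
#'
#' The smallest threshold T in {15, 30, 60, 90} such that every value in
#' the window lies strictly below T fixes the stage (15 -> 5, 30 -> 4,
#' 60 -> 3, 90 -> 2); any value at or above 90 disqualifies the window
#' ("all values under" is strict).
#'
#' @param values Numeric eGFR values inside the window.
#' @return Integer stage 2-5, or `NULL` when no threshold bounds all
#'   values.
#' @examples
#' stage_window(c(25, 28, 22)) # 4
#' stage_window(c(25, 65, 22)) # 2
#' stage_window(c(95, 80))     # NULL
#' @export
stage_window <- function(values) {
  if (length(values) == 0) return(NULL)
  mx <- max(values)
  for (stage in c(5L, 4L, 3L, 2L)) {
    if (mx < egfr_stage_threshold(stage)) return(stage)
  }
  NULL
}

#' Detect and stage chronic kidney disease for a patient
#'
#' The eGFR series is restricted to the year before `index_date`; every
#' window spanning more than 91 days is staged with [stage_window()],
#' and the relevant result is the highest stage with the longest span
#' between mapped values (further ties: earliest window start). A
#' finding is only confirmed when at least one value consistent with
#' the selected stage falls within the 90 days before `index_date`.
#'
#' When no eGFR window qualifies, a history of kidney transplantation
#' or a moderately/severely increased albumin-to-creatinine ratio within
#' the lookback still establishes CKD of unspecified stage (KDIGO's
#' other markers of kidney damage); stage 1 is never assigned because
#' KDIGO defines no limiting eGFR for it.
#'
#' @param patient One-row patient (list or tibble row); only
#'   `transplant_history` is consulted.
#' @param egfr_series Tibble with `value` (mL/min/1.73 m²) and `ts`.
#' @param acr_results List of [compute_acr()] results for the patient.
#' @param index_date POSIXct the diagnosis is anchored to (a case's
#'   discharge when classifying per encounter); defaults to the latest
#'   measurement.
#' @param config Engine constants from [kd_config()].
#' @return `NULL`, or a list of class `ckd_finding` with `stage`
#'   (integer 2-5 or `"unspecified"`), the selected window and its
#'   min/mean/max eGFR, the supporting ACR result if any, and
#'   `evidence` (`"egfr_window"`, `"transplant"` or `"acr_only"`).
#' @export
classify_ckd <- function(patient, egfr_series, acr_results = list(),
                         index_date = NULL, config = kd_config()) {
  if (is.null(index_date)) {
    candidates <- Filter(Negate(is.null), list(
      if (!is.null(egfr_series) && nrow(egfr_series)) max(egfr_series$ts),
      if (length(acr_results)) do.call(max, lapply(acr_results, `[[`, "albumin_ts"))
    ))
    if (!length(candidates)) {
      # no measurement anywhere: only transplant history can establish CKD
      if (isTRUE(patient$transplant_history)) {
        return(structure(
          list(stage = "unspecified", window_start_ts = NULL,
               window_end_ts = NULL, span_hours = NULL, n_values = 0L,
               min_egfr_in_window = NULL, mean_egfr_in_window = NULL,
               max_egfr_in_window = NULL, acr = NULL, evidence = "transplant"),
          class = "ckd_finding"
        ))
      }
      return(NULL)
    }
    index_date <- do.call(max, candidates)
  }
  index_date <- parse_ts(index_date)
  lookback_lo <- index_date - config$ckd.lookback_days * 86400

  acr_in_lookback <- Filter(function(a) {
    a$albumin_ts <= index_date && a$albumin_ts >= lookback_lo
  }, acr_results)
  acr_support <- Filter(function(a) a$category %in% c("A2", "A3"), acr_in_lookback)
  best_acr <- if (length(acr_support)) {
    acr_support[[which.max(vapply(acr_support, `[[`, numeric(1), "acr_mg_per_g"))]]
  } else NULL

  finding <- NULL
  if (!is.null(egfr_series) && nrow(egfr_series) >= 2) {
    ser <- egfr_series[egfr_series$ts <= index_date & egfr_series$ts >= lookback_lo, ]
    if (nrow(ser) >= 2) {
      ser <- ser[order(ser$ts), ]
      windows <- chronic_windows(ser$value, ser$ts, config)
      if (nrow(windows)) {
        windows$stage <- vapply(windows$values, function(v) {
          s <- stage_window(v); if (is.null(s)) NA_integer_ else s
        }, integer(1))
        staged <- windows[!is.na(windows$stage), ]
        if (nrow(staged)) {
          staged <- staged[order(-staged$stage, -staged$span_hours, staged$start_ts), ]
          sel <- staged[1, ]
          ok <- TRUE
          if (isTRUE(config$ckd.require_recency)) {
            recent_lo <- index_date - config$ckd.recency_days * 86400
            thr <- egfr_stage_threshold(sel$stage)
            ok <- any(ser$ts >= recent_lo & ser$ts <= index_date & ser$value < thr)
          }
          if (ok) {
            finding <- structure(
              list(stage = sel$stage,
                   window_start_ts = sel$start_ts, window_end_ts = sel$end_ts,
                   span_hours = sel$span_hours, n_values = sel$n_values,
                   min_egfr_in_window = sel$min_egfr,
                   mean_egfr_in_window = sel$mean_egfr,
                   max_egfr_in_window = sel$max_egfr,
                   acr = best_acr, evidence = "egfr_window"),
              class = "ckd_finding"
            )
          }
        }
      }
    }
  }
  if (!is.null(finding)) return(finding)

  if (isTRUE(patient$transplant_history)) {
    return(structure(
      list(stage = "unspecified", window_start_ts = NULL, window_end_ts = NULL,
           span_hours = NULL, n_values = 0L, min_egfr_in_window = NULL,
           mean_egfr_in_window = NULL, max_egfr_in_window = NULL,
           acr = best_acr, evidence = "transplant"),
      class = "ckd_finding"
    ))
  }
  if (!is.null(best_acr)) {
    return(structure(
      list(stage = "unspecified", window_start_ts = NULL, window_end_ts = NULL,
           span_hours = NULL, n_values = 0L, min_egfr_in_window = NULL,
           mean_egfr_in_window = NULL, max_egfr_in_window = NULL,
           acr = best_acr, evidence = "acr_only"),
      class = "ckd_finding"
    ))
  }
  NULL
}

#' @export
print.ckd_finding <- function(x, ...) {
  if (identical(x$evidence, "egfr_window")) {
    cat(sprintf(
      "<ckd_finding> stage %s over %.0f days (%d values, max eGFR %.1f)\n",
      x$stage, x$span_hours / 24, x$n_values, x$max_egfr_in_window))
  } else {
    cat(sprintf("<ckd_finding> stage %s (evidence: %s)\n", x$stage, x$evidence))
  }
  invisible(x)
}
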