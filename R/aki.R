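#' Baseline serum creatinine for an index admission
#'
#' The baseline is either the lowest creatinine during the
#' hospitalisation or the arithmetic mean of all outpatient creatinine
#' measurements in the 90 days before the index admission; when both are
#' available the lower of the two is used for diagnosis, so that either
#' source may reflect the patient's premorbid kidney function.
#'
#' @param inpatient_values Numeric vector of in-hospital serum
#'   creatinine values (µmol/L) of the encounter.
#' @param outpatient_values Numeric vector of outpatient values in the
#'   90-day lookback before admission (µmol/L).
#' @return A list of class `kd_baseline`: `value` (µmol/L), `method`
#'   (`"inpatient_min"`, `"outpatient_mean_90d"` or `"min_of_both"`),
#'   `source_of_value` (which source supplied the minimum),
#'   `inpatient_min`, `outpatient_mean`, and the two series sizes.
#' @examples
#' baseline_scr(c(88, 70, 95), numeric(0))$value # 70
#' baseline_scr(88, c(60, 64))$value             # 62
#' @export
baseline_scr <- function(inpatient_values, outpatient_values = numeric(0)) {
  inpatient_values <- inpatient_values[!is.na(inpatient_values)]
  outpatient_values <- outpatient_values[!is.na(outpatient_values)]
  n_in <- length(inpatient_values)
  n_out <- length(outpatient_values)
  if (n_in == 0 && n_out == 0) {
    abort("no serum creatinine available for baseline estimation",
          class = "renalrules_no_baseline_error")
  }
  inpatient_min <- if (n_in) min(inpatient_values) else NA_real_
  outpatient_mean <- if (n_out) mean(outpatient_values) else NA_real_
  if (n_in && n_out) {
    method <- "min_of_both"
    value <- min(inpatient_min, outpatient_mean)
    source <- if (outpatient_mean < inpatient_min) "outpatient" else "inpatient"
  } else if (n_in) {
    method <- "inpatient_min"
    value <- inpatient_min
    source <- "inpatient"
  } else {
    method <- "outpatient_mean_90d"
    value <- outpatient_mean
    source <- "outpatient"
  }
  structure(
    list(value = value, method = method, source_of_value = source,
         inpatient_min = inpatient_min, outpatient_mean = outpatient_mean,
         n_inpatient_values = n_in, n_outpatient_values = n_out),
    class = "kd_baseline"
  )
}

#' @export
print.kd_baseline <- function(x, ...) {
  cat(sprintf("<kd_baseline> %.1f µmol/L (%s; %d inpatient, %d outpatient values)\n",
              x$value, x$method, x$n_inpatient_values, x$n_outpatient_values))
  invisible(x)
}

#' Enumerate ordered creatinine pairs within a time window
#'
#' All ordered pairs (earlier, later) of a time-sorted series whose
#' interval does not exceed `max_window_hours`. The staging engine maps
#' every such pair; the count is at most n(n-1)/2.
#'
#' @param values Numeric creatinine values (µmol/L), time order.
#' @param ts POSIXct timestamps matching `values`.
#' @param max_window_hours Window bound in hours (inclusive).
#' @return Tibble with columns `first`, `second`, `first_ts`,
#'   `second_ts`, `interval_hours`.
#' @export
candidate_pairs <- function(values, ts, max_window_hours) {
  n <- length(values)
  stopifnot(length(ts) == n)
  if (n < 2) {
    return(tibble(first = numeric(0), second = numeric(0),
                  first_ts = parse_ts(character(0)),
                  second_ts = parse_ts(character(0)),
                  interval_hours = numeric(0)))
  }
  ord <- order(ts)
  values <- values[ord]; ts <- ts[ord]
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  interval <- hours_between(ts[i], ts[j])
  keep <- interval > 0 & interval <= max_window_hours
  tibble(first = values[i][keep], second = values[j][keep],
         first_ts = ts[i][keep], second_ts = ts[j][keep],
         interval_hours = interval[keep])
}

#' Stage a single creatinine pair under the KDIGO rise criteria
#'
#' With r = second/first, the pair is staged as:
#' \itemize{
#'   \item stage 3, `threshold_crossing_7d`: the pair crosses
#'     353.6 µmol/L (4 mg/dL) from below to above within 7 days;
#'   \item stage 3, `ratio_7d`: r >= 3.0 within 7 days (a rise of 200\%
#'     or more);
#'   \item stage 2, `ratio_7d`: 2.0 <= r < 3.0 within 7 days;
#'   \item stage 1, `ratio_7d`: 1.5 <= r < 2.0 within 7 days;
#'   \item stage 1, `absolute_48h`: second - first >= 26.52 µmol/L
#'     (0.3 mg/dL) within 48 hours.
#' }
#' Ratio bands are half-open upward so each ratio maps to exactly one
#' stage; window bounds are inclusive ("within 48 hours / 7 days").
#' Decreases are never staged.
#'
#' @param first,second Earlier and later creatinine (µmol/L); `first`
#'   must be positive.
#' @param interval_hours Time between the two values, positive.
#' @param config Engine constants from [kd_config()].
#' @return `NULL` if no criterion is met, else `list(stage, criterion)`.
#' @examples
#' stage_from_pair(100, 160, 72)  # stage 1, ratio_7d
#' stage_from_pair(340, 360, 100) # stage 3, threshold_crossing_7d
#' @export
stage_from_pair <- function(first, second, interval_hours, config = kd_config()) {
  if (first <= 0) stop_domain("earlier creatinine value must be positive")
  stopifnot(interval_hours > 0)
  long <- interval_hours <= config$aki.window_long_h
  short <- interval_hours <= config$aki.window_short_h
  thr <- config$aki.stage3_threshold_umol
  r <- second / first
  if (long && first < thr && second > thr) {
    return(list(stage = 3L, criterion = "threshold_crossing_7d"))
  }
  if (long && r >= 3.0) return(list(stage = 3L, criterion = "ratio_7d"))
  if (long && r >= 2.0) return(list(stage = 2L, criterion = "ratio_7d"))
  if (long && r >= 1.5) return(list(stage = 1L, criterion = "ratio_7d"))
  if (short && (second - first) >= config$aki.abs_delta_umol) {
    return(list(stage = 1L, criterion = "absolute_48h"))
  }
  NULL
}

#' Detect and stage acute kidney injury for one encounter
#'
#' Serum creatinine values from 7 days before admission until discharge
#' are paired within the 48-hour and 7-day windows and each pair is
#' staged with [stage_from_pair()]. When the baseline derives from the
#' outpatient mean (and `aki.baseline_as_virtual_pair` is `TRUE`), the
#' baseline is additionally injected as a virtual earlier value against
#' every in-window measurement, with the 7-day presumption satisfied;
#' virtual pairs can never trigger the 48-hour absolute criterion and
#' always lose minimum-interval ties to real pairs (their interval is
#' pinned to the 7-day bound).
#'
#' The reported finding is the highest stage, ties broken by the
#' shortest interval between the mapped values, then by the earliest
#' later timestamp. Encounters with no creatinine measurement are
#' classified as not having AKI (`NULL`).
#'
#' @param encounter One-row encounter (list or tibble row) with
#'   `admit_ts` and `discharge_ts`.
#' @param scr_series Tibble of the patient's serum creatinine with
#'   columns `value` (µmol/L) and `ts` (POSIXct).
#' @param baseline A [baseline_scr()] result, or `NULL` to estimate it
#'   from `scr_series` and the encounter window.
#' @param config Engine constants from [kd_config()].
#' @return `NULL`, or a list of class `aki_finding` with the stage,
#'   criterion, value pair, timestamps, interval and baseline.
#' @export
classify_aki <- function(encounter, scr_series, baseline = NULL,
                         config = kd_config()) {
  admit <- parse_ts(encounter$admit_ts)
  discharge <- parse_ts(encounter$discharge_ts)
  if (nrow(scr_series) == 0) return(NULL)
  scr_series <- scr_series[order(scr_series$ts), ]

  lo <- admit - config$aki.preadmission_lookback_h * 3600
  in_window <- scr_series$ts >= lo & scr_series$ts <= discharge
  ser <- scr_series[in_window, ]
  if (nrow(ser) == 0) return(NULL)

  if (is.null(baseline)) {
    inpat <- scr_series$value[scr_series$ts >= admit & scr_series$ts <= discharge]
    out_lo <- admit - config$aki.baseline_lookback_days * 86400
    outpat <- scr_series$value[scr_series$ts >= out_lo & scr_series$ts < admit]
    if (length(inpat) == 0 && length(outpat) == 0) return(NULL)
    baseline <- baseline_scr(inpat, outpat)
  }

  pairs <- candidate_pairs(ser$value, ser$ts, config$aki.window_long_h)
  pairs$virtual <- rep(FALSE, nrow(pairs))
  if (isTRUE(config$aki.baseline_as_virtual_pair) &&
      baseline$source_of_value == "outpatient" && baseline$value > 0) {
    virt <- tibble(
      first = baseline$value, second = ser$value,
      first_ts = ser$ts - config$aki.window_long_h * 3600,
      second_ts = ser$ts,
      interval_hours = config$aki.window_long_h,
      virtual = TRUE
    )
    pairs <- bind_rows(pairs, virt)
  }
  if (nrow(pairs) == 0) return(NULL)

  best <- NULL
  for (k in seq_len(nrow(pairs))) {
    if (pairs$first[k] <= 0) next
    st <- stage_from_pair(pairs$first[k], pairs$second[k],
                          pairs$interval_hours[k], config)
    if (is.null(st)) next
    cand <- list(stage = st$stage, criterion = st$criterion,
                 first_value = pairs$first[k], second_value = pairs$second[k],
                 first_ts = pairs$first_ts[k], second_ts = pairs$second_ts[k],
                 interval_hours = pairs$interval_hours[k],
                 virtual_baseline_pair = pairs$virtual[k])
    if (is.null(best) ||
        cand$stage > best$stage ||
        (cand$stage == best$stage && cand$interval_hours < best$interval_hours) ||
        (cand$stage == best$stage && cand$interval_hours == best$interval_hours &&
         cand$second_ts < best$second_ts)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best$baseline <- baseline
  structure(best, class = "aki_finding")
}

#' @export
print.aki_finding <- function(x, ...) {
  cat(sprintf(
    "<aki_finding> stage %d (%s): %.1f -> %.1f µmol/L over %.1f h\n",
    x$stage, x$criterion, x$first_value, x$second_value, x$interval_hours))
  invisible(x)
}
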