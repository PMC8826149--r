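#' Engine configuration with documented defaults
#'
#' One flat list of every tunable constant used by the staging engines,
#' the text audit and the reporting module. Values are the KDIGO-derived
#' defaults; any subset can be overridden, either programmatically or from
#' a YAML file via [read_config()].
#'
#' @details
#' Keys and defaults:
#' \describe{
#'   \item{aki.window_short_h}{48 — window (hours) for the absolute-rise
#'     criterion (0.3 mg/dL).}
#'   \item{aki.window_long_h}{168 — window (hours, 7 days) for the
#'     ratio and threshold-crossing criteria.}
#'   \item{aki.abs_delta_umol}{26.52 — absolute creatinine rise
#'     (µmol/L) that defines stage 1 within 48 h.}
#'   \item{aki.stage3_threshold_umol}{353.6 — the 4 mg/dL bound whose
#'     crossing within 7 days defines stage 3.}
#'   \item{aki.baseline_lookback_days}{90 — outpatient lookback before the
#'     index admission for the baseline mean.}
#'   \item{aki.preadmission_lookback_h}{168 — serum-creatinine values this
#'     many hours before admission participate in pair mapping.}
#'   \item{aki.baseline_as_virtual_pair}{TRUE — inject an outpatient-mean
#'     baseline as a virtual earlier value (see the methods vignette).}
#'   \item{ckd.chronicity_days}{91 — eGFR windows must span strictly more
#'     than this many days.}
#'   \item{ckd.recency_days}{90 — a value consistent with the selected
#'     stage must fall within this many days before the index date.}
#'   \item{ckd.lookback_days}{365 — eGFR series lookback before the index
#'     date.}
#'   \item{ckd.thresholds}{c(90, 60, 30, 15) — upper eGFR bounds
#'     (mL/min/1.73 m²) for stages 2/3/4/5.}
#'   \item{ckd.require_recency}{TRUE — apply the recency constraint to
#'     every finding.}
#'   \item{acr.a2_low}{3 — ACR (mg/g) lower bound of the moderately
#'     increased category.}
#'   \item{acr.a3_low}{30 — ACR (mg/g) above which albuminuria is severely
#'     increased.}
#'   \item{acr.pairing_hours}{720 — maximum albumin/creatinine pairing
#'     interval (30 days).}
#'   \item{conversion.scr_factor}{88.4 — µmol/L per mg/dL of creatinine.}
#'   \item{reporting.rounding}{"half_up" — rounding convention of printed
#'     percentages.}
#' }
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @examples
#' cfg <- kd_config(ckd.recency_days = 120)
#' cfg$ckd.recency_days
#' @export
kd_config <- function(...) {
  defaults <- list(
    aki.window_short_h = 48,
    aki.window_long_h = 168,
    aki.abs_delta_umol = 26.52,
    aki.stage3_threshold_umol = 353.6,
    aki.baseline_lookback_days = 90,
    aki.preadmission_lookback_h = 168,
    aki.baseline_as_virtual_pair = TRUE,
    ckd.chronicity_days = 91,
    ckd.recency_days = 90,
    ckd.lookback_days = 365,
    ckd.thresholds = c(90, 60, 30, 15),
    ckd.require_recency = TRUE,
    acr.a2_low = 3,
    acr.a3_low = 30,
    acr.pairing_hours = 720,
    conversion.scr_factor = 88.4,
    reporting.rounding = "half_up"
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  defaults
}

#' Read engine configuration from a YAML file
#'
#' Keys absent from the file keep their [kd_config()] defaults. Nested
#' YAML maps are flattened with a dot separator so that
#' `aki: {window_short_h: 48}` and `aki.window_short_h: 48` are
#' equivalent.
#'
#' @param path Path to a YAML file.
#' @return Named list as from [kd_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  flat <- flatten_keys(raw)
  do.call(kd_config, flat)
}

flatten_keys <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    val <- x[[nm]]
    if (is.list(val) && !is.null(names(val))) {
      out <- c(out, flatten_keys(val, key))
    } else {
      out[[key]] <- unlist(val)
    }
  }
  out
}
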