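SCR_MGDL_TO_UMOL <- 88.4   # µmol/L per mg/dL of creatinine (molar mass 113.12 g/mol)
URINE_CREA_MMOL_TO_GL <- 113.12 / 1000  # g/L per mmol/L

#' Convert serum creatinine between mg/dL and µmol/L
#'
#' The conversion factor 88.4 is the one consistent with both KDIGO
#' threshold pairs in clinical use: 0.3 mg/dL = 26.52 µmol/L and
#' 4 mg/dL = 353.6 µmol/L.
#'
#' @param value Creatinine concentration, non-negative.
#' @return The converted concentration.
#' @examples
#' creatinine_mgdl_to_umol(0.3) # 26.52
#' creatinine_mgdl_to_umol(4)   # 353.6
#' @export
creatinine_mgdl_to_umol <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop_domain("creatinine must be non-negative")
  value * SCR_MGDL_TO_UMOL
}

#' @rdname creatinine_mgdl_to_umol
#' @export
creatinine_umol_to_mgdl <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop_domain("creatinine must be non-negative")
  value / SCR_MGDL_TO_UMOL
}

#' Estimate GFR with the 2009 CKD-EPI creatinine equation
#'
#' eGFR = 141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 *
#' 0.993^age * 1.018 (if female) * 1.159 (if black), with kappa = 0.7
#' (female) / 0.9 (male) and alpha = -0.329 / -0.411. The race coefficient
#' sits behind an explicit flag defaulting to `FALSE`; modern practice
#' omits it, and the 2021 race-free refit is out of scope.
#'
#' @param scr_mgdl Serum creatinine in mg/dL (convert with
#'   [creatinine_umol_to_mgdl()] if needed), strictly positive.
#' @param age Age in years, >= 18 (the adult equation only).
#' @param sex "female" or "male".
#' @param black_race Apply the 1.159 coefficient of the 2009 equation.
#' @return eGFR in mL/min/1.73 m².
#' @examples
#' ckd_epi_egfr(0.7, age = 50, sex = "female") # 141 * 0.993^50 * 1.018
#' @export
ckd_epi_egfr <- function(scr_mgdl, age, sex, black_race = FALSE) {
  sex <- match.arg(sex, c("female", "male"))
  if (any(scr_mgdl <= 0)) stop_domain("serum creatinine must be positive")
  if (any(age < 18)) {
    abort("CKD-EPI supports adults only (age >= 18)",
          class = "renalrules_unsupported_population_error")
  }
  kappa <- if (sex == "female") 0.7 else 0.9
  alpha <- if (sex == "female") -0.329 else -0.411
  gfr <- 141 *
    pmin(scr_mgdl / kappa, 1)^alpha *
    pmax(scr_mgdl / kappa, 1)^-1.209 *
    0.993^age
  if (sex == "female") gfr <- gfr * 1.018
  if (isTRUE(black_race)) gfr <- gfr * 1.159
  gfr
}

#' Upper eGFR bound of a CKD GFR category
#'
#' Stages 2-5 are bounded above by 90/60/30/15 mL/min/1.73 m²; KDIGO
#' defines no limiting eGFR for stage 1, so requesting it is an error.
#'
#' @param stage CKD stage, one of 2, 3, 4, 5.
#' @return Threshold in mL/min/1.73 m².
#' @examples
#' egfr_stage_threshold(3) # 60
#' @export
egfr_stage_threshold <- function(stage) {
  thresholds <- c(`2` = 90, `3` = 60, `4` = 30, `5` = 15)
  if (length(stage) != 1 || !stage %in% c(2, 3, 4, 5)) {
    abort("no limiting eGFR is defined for this stage (stages 2-5 only)",
          class = "renalrules_unsupported_stage_error")
  }
  unname(thresholds[as.character(stage)])
}

#' Urinary albumin-to-creatinine ratio and its KDIGO category
#'
#' ACR in mg/g is urinary albumin (mg/L) divided by urinary creatinine
#' (g/L); creatinine reported in mmol/L is first converted via the molar
#' mass 113.12 g/mol. Categories: A1 (normal to mildly increased) below
#' 3 mg/g, A2 (moderately increased) between 3 and 30 mg/g inclusive,
#' A3 (severely increased) above 30 mg/g. Albumin and creatinine must
#' come from one sample or from samples at most 30 days apart.
#'
#' @param albumin A one-row lab measurement (or list) with `value` in
#'   mg/L and `ts`; analyte urine_albumin.
#' @param creatinine Companion urine_creatinine measurement, `value` in
#'   g/L or mmol/L per its `unit` field (g/L assumed when absent).
#' @return A list of class `acr_result` with fields `acr_mg_per_g`,
#'   `category` ("A1", "A2" or "A3"), `albumin_ts`, `creatinine_ts` and
#'   `pairing_interval_hours`.
#' @examples
#' a <- list(value = 60, ts = as.POSIXct("2019-01-01", tz = "UTC"))
#' c <- list(value = 1, unit = "g/L", ts = as.POSIXct("2019-01-02", tz = "UTC"))
#' compute_acr(a, c)$category # "A3"
#' @export
compute_acr <- function(albumin, creatinine) {
  alb_ts <- parse_ts(albumin$ts)
  cre_ts <- parse_ts(creatinine$ts)
  interval <- abs(hours_between(alb_ts, cre_ts))
  if (interval > 720) {
    abort("albumin/creatinine pairing interval exceeds 30 days",
          class = "renalrules_pairing_error")
  }
  cre_val <- creatinine$value
  unit <- creatinine$unit %||% "g/L"
  if (identical(unit, "mmol/L")) cre_val <- cre_val * URINE_CREA_MMOL_TO_GL
  else if (!identical(unit, "g/L")) stop_unit(paste0("unknown urine creatinine unit: ", unit))
  if (cre_val == 0) {
    abort("urine creatinine is zero; ACR undefined",
          class = "renalrules_division_error")
  }
  acr <- albumin$value / cre_val
  structure(
    list(
      acr_mg_per_g = acr,
      category = acr_category(acr),
      albumin_ts = alb_ts,
      creatinine_ts = cre_ts,
      pairing_interval_hours = interval
    ),
    class = "acr_result"
  )
}

#' @rdname compute_acr
#' @param acr_mg_per_g Numeric ACR value(s) in mg/g.
#' @export
acr_category <- function(acr_mg_per_g) {
  ifelse(acr_mg_per_g > 30, "A3", ifelse(acr_mg_per_g >= 3, "A2", "A1"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.acr_result <- function(x, ...) {
  cat(sprintf("ACR %.2f mg/g (%s), pairing interval %.1f h\n",
              x$acr_mg_per_g, x$category, x$pairing_interval_hours))
  invisible(x)
}
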