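#' Synthetic cohort generator configuration
#'
#' Defines the composition of a generated cohort: the share of healthy
#' patients, of AKI episodes (split evenly over the five stage/criterion
#' profiles), of CKD profiles (GFR stages 2-5 plus transplant-history
#' and albuminuria-only patients) and of acute-on-chronic combinations,
#' together with the measurement noise (coefficient of variation of
#' stationary creatinine/eGFR) and the misspelling rate of planted
#' report terms.
#'
#' Trajectories are piecewise constant with event jumps: every injected
#' episode is constructed, with margin from the band edges, to satisfy
#' exactly its labelled stage and criterion and no higher stage, so the
#' generated truth labels are exact by construction. Configurations
#' whose noise would let a stationary series cross a staging threshold
#' are rejected with a feasibility error.
#'
#' @param n_patients Cohort size.
#' @param frac_healthy,frac_aki,frac_ckd,frac_acute_on_chronic
#'   Composition fractions (must sum to 1).
#' @param noise Coefficient of variation of stationary series; must be
#'   below 0.05 so that no healthy pair and no injected episode can
#'   drift across a staging boundary.
#' @param misspelling_rate Probability that a planted report term is
#'   perturbed by exactly one adjacent transposition or substitution.
#' @return Named list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 200,
                         frac_healthy = 0.40, frac_aki = 0.25,
                         frac_ckd = 0.25, frac_acute_on_chronic = 0.10,
                         noise = 0, misspelling_rate = 0.3) {
  if (abs(frac_healthy + frac_aki + frac_ckd + frac_acute_on_chronic - 1) > 1e-9) {
    stop_config("composition fractions must sum to 1")
  }
  if (noise < 0 || misspelling_rate < 0 || misspelling_rate > 1) {
    stop_config("noise must be >= 0 and misspelling_rate in [0, 1]")
  }
  if (noise >= 0.05) {
    abort(paste0(
      "noise ", noise, " infeasible: a stationary series could cross a ",
      "staging bound (e.g. an absolute-criterion stage 1 episode would ",
      "drift into the stage 1 ratio band)"),
      class = "renalrules_feasibility_error")
  }
  structure(
    list(n_patients = n_patients, frac_healthy = frac_healthy,
         frac_aki = frac_aki, frac_ckd = frac_ckd,
         frac_acute_on_chronic = frac_acute_on_chronic,
         noise = noise, misspelling_rate = misspelling_rate),
    class = "synth_config"
  )
}

AKI_PROFILES <- data.frame(
  stage = c(1L, 1L, 2L, 3L, 3L),
  criterion = c("absolute_48h", "ratio_7d", "ratio_7d", "ratio_7d",
                "threshold_crossing_7d"),
  stringsAsFactors = FALSE
)
CKD_PROFILES <- c("2", "3", "4", "5", "transplant", "acr_only")
# mid-band eGFR per stage, with margin from both category bounds
CKD_BAND_CENTER <- c(`2` = 75, `3` = 45, `4` = 22, `5` = 10)

#' Inject an AKI episode into a stationary creatinine series
#'
#' Replaces the measurement at `peak_index` with a value engineered so
#' that the series' maximal finding under the staging rules is exactly
#' the requested stage and criterion: an absolute rise of 30 µmol/L for
#' the 48-hour criterion (ratio kept below 1.5), ratios 1.7/2.5/3.5 for
#' the stage 1/2/3 bands (margin from every bound), and a jump from a
#' 330 µmol/L plateau to 380 µmol/L for the 4 mg/dL threshold crossing.
#'
#' @param values Stationary creatinine series (µmol/L).
#' @param stage Target stage 1-3.
#' @param criterion Target criterion.
#' @param base The series' plateau value.
#' @param peak_index Position of the injected peak (needs at least one
#'   earlier value within 48 hours for the absolute criterion).
#' @return Modified values vector.
#' @export
inject_aki_episode <- function(values, stage, criterion, base,
                               peak_index = min(4L, length(values))) {
  key <- paste(stage, criterion)
  peak <- switch(
    key,
    "1 absolute_48h" = {
      if (base <= 80 || peak_index < 2) {
        abort(paste0("absolute-criterion injection needs base > 80 µmol/L ",
                     "and an earlier value so the ratio stays below 1.5"),
              class = "renalrules_feasibility_error")
      }
      # anchor to the observed plateau so the 26.52 delta holds under noise
      max(values[max(1, peak_index - 2):(peak_index - 1)]) + 30
    },
    "1 ratio_7d" = base * 1.7,
    "2 ratio_7d" = base * 2.5,
    "3 ratio_7d" = base * 3.5,
    "3 threshold_crossing_7d" = 380,
    abort(paste0("no injection profile for stage ", stage, " / ", criterion),
          class = "renalrules_feasibility_error")
  )
  values[peak_index] <- peak
  values
}

#' Build an eGFR series establishing a CKD stage
#'
#' Values sit mid-band for the requested GFR category over a span well
#' beyond 91 days (outpatient values 200/150/100 days before admission
#' plus an in-hospital confirmation one day after admission, inside the
#' 90-day recency window of a discharge-anchored diagnosis).
#'
#' @param stage CKD stage 2-5.
#' @param admit_ts Admission timestamp the series is anchored to.
#' @param noise Coefficient of variation of the stationary values.
#' @return Tibble with `value` and `ts`.
#' @export
inject_ckd_profile <- function(stage, admit_ts, noise = 0) {
  center <- CKD_BAND_CENTER[[as.character(stage)]]
  offsets_days <- c(-200, -150, -100, 1)
  vals <- center * (1 + stats::runif(length(offsets_days), -noise, noise))
  upper <- egfr_stage_threshold(as.integer(stage))
  lower <- if (as.integer(stage) < 5) egfr_stage_threshold(as.integer(stage) + 1) else 0
  if (any(vals >= upper - 0.5) || any(vals <= lower + 0.5)) {
    abort("noise pushes eGFR out of the target GFR category band",
          class = "renalrules_feasibility_error")
  }
  tibble(value = vals, ts = admit_ts + offsets_days * 86400)
}

plantable_terms <- function(aki_stage, ckd_stage) {
  terms <- character(0)
  if (!is.na(aki_stage)) {
    terms <- c(terms, "aki", "kreatinin")
    if (aki_stage == 3L) terms <- c(terms, "nierenversagen")
  }
  if (!is.na(ckd_stage)) {
    terms <- c(terms, "niereninsuffizienz")
    if (ckd_stage %in% c("2", "3", "4", "5")) terms <- c(terms, "ckd", "egfr", "kdigo")
  }
  unique(terms)
}

perturb_term <- function(term) {
  chars <- strsplit(term, "", fixed = TRUE)[[1]]
  n <- length(chars)
  transposable <- which(chars[-n] != chars[-1])
  if (length(transposable) && stats::runif(1) < 0.5) {
    i <- if (length(transposable) == 1) transposable else sample(transposable, 1)
    tmp <- chars[i]; chars[i] <- chars[i + 1]; chars[i + 1] <- tmp
  } else {
    i <- sample.int(n, 1)
    chars[i] <- sample(setdiff(letters, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Render synthetic discharge reports from truth labels
#'
#' Each labelled case's report contains its planted terms exactly once;
#' with probability `misspelling_rate` a word term is perturbed by one
#' adjacent transposition or substitution (restricted
#' Damerau-Levenshtein distance exactly 1 from the canonical spelling).
#' Staged CKD cases additionally carry an exact KDIGO staging token
#' (e.g. `G3A1`). Healthy cases get a report without renal terms.
#'
#' @param truth Truth-label tibble from [generate_cohort()].
#' @param encounters Encounter table supplying report dates.
#' @param misspelling_rate Probability in `[0, 1]`.
#' @return List with `reports` (tibble
#'   `case_id,report_ts,report_type,text`) and `planted` (tibble
#'   `case_id,term,misspelled,token`).
#' @export
render_reports <- function(truth, encounters, misspelling_rate = 0) {
  reports <- list(); planted <- list()
  enc_by_case <- stats::setNames(seq_len(nrow(encounters)), encounters$case_id)
  for (k in seq_len(nrow(truth))) {
    case_id <- truth$case_id[k]
    enc <- encounters[enc_by_case[[case_id]], ]
    terms <- plantable_terms(truth$true_aki_stage[k], truth$true_ckd_stage[k])
    tokens <- character(0)
    for (term in terms) {
      misspell <- stats::runif(1) < misspelling_rate
      token <- if (misspell) perturb_term(term) else term
      tokens <- c(tokens, token)
      planted[[length(planted) + 1]] <- tibble(
        case_id = case_id, term = term, misspelled = misspell, token = token)
    }
    if (!is.na(truth$true_ckd_stage[k]) &&
        truth$true_ckd_stage[k] %in% c("2", "3", "4", "5")) {
      staging <- paste0("G", truth$true_ckd_stage[k], "A1")
      tokens <- c(tokens, staging)
      planted[[length(planted) + 1]] <- tibble(
        case_id = case_id, term = "G[1-5]A[1-3]", misspelled = FALSE,
        token = staging)
    }
    body <- if (length(tokens)) {
      paste0("Diagnose und Befund: ", paste(tokens, collapse = ", "),
             ". Verlauf siehe Labor.")
    } else {
      "Patient in gutem Allgemeinzustand entlassen. Keine renale Diagnose."
    }
    reports[[k]] <- tibble(
      case_id = case_id, report_ts = enc$discharge_ts,
      report_type = "discharge_letter",
      text = paste0("Entlassungsbericht. ", body)
    )
  }
  list(
    reports = bind_rows(reports),
    planted = if (length(planted)) bind_rows(planted) else
      tibble(case_id = character(0), term = character(0),
             misspelled = logical(0), token = character(0))
  )
}

#' Generate a synthetic cohort with ground-truth labels
#'
#' Builds patients, one inpatient encounter each, serum-creatinine and
#' eGFR series (plus urine albumin/creatinine pairs for
#' albuminuria-only patients), discharge reports with planted renal
#' terms, and a truth table recording the engineered AKI stage and
#' criterion, CKD stage, acute-on-chronic flag and planted terms per
#' case. Deterministic for a fixed seed: a single `set.seed(seed)` at
#' entry drives every draw.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List with `cohort` (a validated `kd_cohort`), `truth`
#'   (tibble, one row per case) and `planted` (per-term planting
#'   bookkeeping from [render_reports()]).
#' @examples
#' g <- generate_cohort(synth_config(n_patients = 10), seed = 1)
#' g$cohort
#' @export
generate_cohort <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_patients

  n_aki <- round(config$frac_aki * n)
  n_ckd <- round(config$frac_ckd * n)
  n_aoc <- round(config$frac_acute_on_chronic * n)
  n_healthy <- n - n_aki - n_ckd - n_aoc
  if (n_healthy < 0) stop_config("composition fractions exceed cohort size")

  profile <- c(
    rep("healthy", n_healthy),
    paste0("aki:", rep_len(seq_len(nrow(AKI_PROFILES)), n_aki)),
    paste0("ckd:", rep_len(CKD_PROFILES, n_ckd)),
    paste0("aoc:", rep_len(seq_len(nrow(AKI_PROFILES)), n_aoc), ":",
           rep_len(c("2", "3", "4", "5"), n_aoc))
  )
  profile <- sample(profile)  # shuffle so period assignment is unconfounded

  patients <- list(); encounters <- list(); labs <- list(); truth <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    cid <- sprintf("C%04d", i)
    sex <- sample(c("female", "male"), 1)
    age <- sample(30:90, 1)
    year <- sample(c(2018, 2019), 1)
    admit <- as.POSIXct(sprintf("%d-01-05 08:00:00", year), tz = "UTC") +
      sample(0:320, 1) * 86400
    stay_days <- 9L
    discharge <- admit + stay_days * 86400 + 8 * 3600
    birth_date <- as.Date(admit) - round(age * 365.25)

    parts <- strsplit(profile[i], ":", fixed = TRUE)[[1]]
    kind <- parts[1]
    aki_idx <- NA_integer_; ckd_prof <- NA_character_
    if (kind == "aki") aki_idx <- as.integer(parts[2])
    if (kind == "ckd") ckd_prof <- parts[2]
    if (kind == "aoc") { aki_idx <- as.integer(parts[2]); ckd_prof <- parts[3] }

    aki_stage <- if (!is.na(aki_idx)) AKI_PROFILES$stage[aki_idx] else NA_integer_
    aki_criterion <- if (!is.na(aki_idx)) AKI_PROFILES$criterion[aki_idx] else NA_character_
    ckd_stage <- if (!is.na(ckd_prof)) {
      if (ckd_prof %in% c("transplant", "acr_only")) "unspecified" else ckd_prof
    } else NA_character_
    transplant <- identical(ckd_prof, "transplant")

    # --- serum creatinine -------------------------------------------------
    crossing <- identical(aki_criterion, "threshold_crossing_7d")
    absolute <- identical(aki_criterion, "absolute_48h")
    base <- if (crossing) 330
            else if (absolute) stats::runif(1, 85, 100)
            else stats::runif(1, 70, 100)
    scr_ts <- admit + (0:stay_days) * 86400            # daily at 08:00
    scr_vals <- base * (1 + stats::runif(length(scr_ts), -config$noise, config$noise))
    if (crossing) scr_vals <- pmin(scr_vals, 352)      # plateau stays under 4 mg/dL
    if (!is.na(aki_idx)) {
      scr_vals <- inject_aki_episode(scr_vals, aki_stage, aki_criterion, base)
    }
    # two outpatient values at the plateau, 30 and 20 days before admission
    out_ts <- admit - c(30, 20) * 86400
    out_vals <- base * (1 + stats::runif(2, -config$noise, config$noise))
    labs[[length(labs) + 1]] <- tibble(
      patient_id = pid,
      case_id = c(rep(NA_character_, 2), rep(cid, length(scr_ts))),
      analyte = "scr",
      value = c(out_vals, scr_vals),
      unit = "µmol/L",
      ts = c(out_ts, scr_ts),
      setting = c(rep("outpatient", 2), rep("inpatient", length(scr_ts)))
    )

    # --- eGFR -------------------------------------------------------------
    if (!is.na(ckd_prof) && ckd_prof %in% c("2", "3", "4", "5")) {
      egfr <- inject_ckd_profile(ckd_prof, admit, config$noise)
    } else {
      # normal kidney filtration: one pre-admission and one in-hospital value
      center <- stats::runif(1, 100, 110)
      egfr <- tibble(
        value = center * (1 + stats::runif(2, -config$noise, config$noise)),
        ts = admit + c(-120, 1) * 86400
      )
      if (any(egfr$value < 90)) {
        abort("noise pushed a healthy eGFR below 90", # guarded by synth_config
              class = "renalrules_feasibility_error")
      }
    }
    labs[[length(labs) + 1]] <- tibble(
      patient_id = pid,
      case_id = ifelse(egfr$ts >= admit & egfr$ts <= discharge, cid, NA_character_),
      analyte = "egfr", value = egfr$value, unit = "mL/min/1.73m²",
      ts = egfr$ts,
      setting = ifelse(egfr$ts >= admit & egfr$ts <= discharge,
                       "inpatient", "outpatient")
    )

    # --- urine albumin / creatinine for albuminuria-only CKD ---------------
    if (identical(ckd_prof, "acr_only")) {
      sample_ts <- admit + 86400
      labs[[length(labs) + 1]] <- tibble(
        patient_id = pid, case_id = cid,
        analyte = c("urine_albumin", "urine_creatinine"),
        value = c(80, 1), unit = c("mg/L", "g/L"),
        ts = rep(sample_ts, 2), setting = "inpatient"
      )
    }

    patients[[i]] <- tibble(
      patient_id = pid, birth_date = birth_date, sex = sex,
      black_race = FALSE, transplant_history = transplant
    )
    encounters[[i]] <- tibble(
      case_id = cid, patient_id = pid, admit_ts = admit, discharge_ts = discharge
    )
    truth[[i]] <- tibble(
      case_id = cid, patient_id = pid,
      true_aki_stage = aki_stage, true_aki_criterion = aki_criterion,
      true_ckd_stage = ckd_stage,
      true_acute_on_chronic = !is.na(aki_stage) && !is.na(ckd_stage)
    )
  }

  patients <- bind_rows(patients)
  encounters <- bind_rows(encounters)
  labs <- bind_rows(labs)
  truth <- bind_rows(truth)

  rendered <- render_reports(truth, encounters, config$misspelling_rate)
  planted_by_case <- rendered$planted |>
    group_by(.data$case_id) |>
    summarise(
      planted_terms = paste(.data$term, collapse = ";"),
      misspelled_terms = paste(.data$term[.data$misspelled], collapse = ";"),
      .groups = "drop"
    )
  truth <- truth |>
    left_join(planted_by_case, by = "case_id") |>
    mutate(planted_terms = ifelse(is.na(.data$planted_terms), "", .data$planted_terms),
           misspelled_terms = ifelse(is.na(.data$misspelled_terms), "",
                                     .data$misspelled_terms))

  cohort <- as_kd_cohort(patients, encounters, labs, rendered$reports)
  list(cohort = cohort, truth = truth, planted = rendered$planted)
}
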