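# Independent brute-force oracles. These re-derive the staging rules and
# edit distances from their definitions, by a different route than the
# package implementation, so that agreement is evidence of correctness.

ts0 <- function(hours) as.POSIXct("2019-01-01 00:00:00", tz = "UTC") + hours * 3600

# --- restricted Damerau-Levenshtein via memoized recursion -------------------
osa_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av); lb <- length(bv)
  memo <- matrix(NA_integer_, la + 1, lb + 1)
  rec <- function(i, j) { # distance between prefixes a[1..i], b[1..j]
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    if (i == 0) r <- j
    else if (j == 0) r <- i
    else {
      cost <- if (av[i] == bv[j]) 0L else 1L
      r <- min(rec(i - 1, j) + 1L, rec(i, j - 1) + 1L, rec(i - 1, j - 1) + cost)
      if (i > 1 && j > 1 && av[i] == bv[j - 1] && av[i - 1] == bv[j]) {
        r <- min(r, rec(i - 2, j - 2) + 1L)
      }
    }
    memo[i + 1, j + 1] <<- r
    r
  }
  as.integer(rec(la, lb))
}

# --- AKI: stage one ordered pair straight from the rule definitions ----------
oracle_stage_pair <- function(first, second, hours) {
  if (first <= 0) return(NULL)
  within7d <- hours <= 168
  within48h <- hours <= 48
  ratio <- second / first
  if (within7d && first < 353.6 && second > 353.6) {
    return(list(stage = 3L, criterion = "threshold_crossing_7d"))
  }
  if (within7d && ratio >= 3) return(list(stage = 3L, criterion = "ratio_7d"))
  if (within7d && ratio >= 2) return(list(stage = 2L, criterion = "ratio_7d"))
  if (within7d && ratio >= 1.5) return(list(stage = 1L, criterion = "ratio_7d"))
  if (within48h && second - first >= 26.52) {
    return(list(stage = 1L, criterion = "absolute_48h"))
  }
  NULL
}

# Enumerate every ordered pair of the restricted series (plus virtual
# baseline pairs), stage each, and select max stage / min interval /
# earliest later timestamp.
oracle_classify_aki <- function(encounter, scr_series, baseline = NULL) {
  admit <- encounter$admit_ts
  discharge <- encounter$discharge_ts
  if (nrow(scr_series) == 0) return(NULL)
  keep <- scr_series$ts >= admit - 168 * 3600 & scr_series$ts <= discharge
  ser <- scr_series[keep, ]
  ser <- ser[order(ser$ts), ]
  if (nrow(ser) == 0) return(NULL)
  if (is.null(baseline)) {
    inp <- scr_series$value[scr_series$ts >= admit & scr_series$ts <= discharge]
    outp <- scr_series$value[scr_series$ts < admit &
                               scr_series$ts >= admit - 90 * 86400]
    if (!length(inp) && !length(outp)) return(NULL)
    baseline <- baseline_scr(inp, outp)
  }
  cands <- list()
  n <- nrow(ser)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      h <- as.numeric(difftime(ser$ts[j], ser$ts[i], units = "hours"))
      if (h <= 0 || h > 168) next
      st <- oracle_stage_pair(ser$value[i], ser$value[j], h)
      if (!is.null(st)) {
        cands[[length(cands) + 1]] <- list(
          stage = st$stage, criterion = st$criterion, interval = h,
          second_ts = ser$ts[j], first = ser$value[i], second = ser$value[j])
      }
    }
  }
  if (baseline$source_of_value == "outpatient" && baseline$value > 0) {
    for (j in seq_len(n)) {
      st <- oracle_stage_pair(baseline$value, ser$value[j], 168)
      if (!is.null(st)) {
        cands[[length(cands) + 1]] <- list(
          stage = st$stage, criterion = st$criterion, interval = 168,
          second_ts = ser$ts[j], first = baseline$value, second = ser$value[j])
      }
    }
  }
  if (!length(cands)) return(NULL)
  best <- cands[[1]]
  for (cand in cands[-1]) {
    if (cand$stage > best$stage ||
        (cand$stage == best$stage && cand$interval < best$interval) ||
        (cand$stage == best$stage && cand$interval == best$interval &&
         cand$second_ts < best$second_ts)) {
      best <- cand
    }
  }
  best
}

# --- CKD: enumerate all >91-day windows, stage, select -----------------------
oracle_classify_ckd <- function(values, ts, index_date, recency = TRUE) {
  keep <- ts <= index_date & ts >= index_date - 365 * 86400
  values <- values[keep]; ts <- ts[keep]
  ord <- order(ts); values <- values[ord]; ts <- ts[ord]
  n <- length(values)
  if (n < 2) return(NULL)
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    span <- as.numeric(difftime(ts[j], ts[i], units = "hours"))
    if (span <= 91 * 24) next
    inside <- values[ts >= ts[i] & ts <= ts[j]]
    stage <- if (all(inside < 15)) 5L else if (all(inside < 30)) 4L else
      if (all(inside < 60)) 3L else if (all(inside < 90)) 2L else NULL
    if (is.null(stage)) next
    cand <- list(stage = stage, span = span, start = ts[i], end = ts[j])
    if (is.null(best) || cand$stage > best$stage ||
        (cand$stage == best$stage && cand$span > best$span) ||
        (cand$stage == best$stage && cand$span == best$span &&
         cand$start < best$start)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  if (recency) {
    thr <- c(`2` = 90, `3` = 60, `4` = 30, `5` = 15)[[as.character(best$stage)]]
    recent <- ts >= index_date - 90 * 86400 & ts <= index_date & values < thr
    if (!any(recent)) return(NULL)
  }
  best
}

# random series builders used by the property suites
random_scr_series <- function(n) {
  hours <- sort(stats::runif(n, 0, 260))
  tibble::tibble(value = stats::runif(n, 40, 450), ts = ts0(hours))
}

random_egfr_series <- function(n) {
  days <- sort(stats::runif(n, 0, 400))
  tibble::tibble(value = stats::runif(n, 5, 120), ts = ts0(days * 24))
}
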