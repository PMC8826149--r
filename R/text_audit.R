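#' Damerau-Levenshtein string distance
#'
#' Minimal number of single-character insertions, deletions,
#' substitutions and adjacent transpositions transforming `a` into `b`.
#' Two variants are provided: the restricted distance
#' (`method = "osa"`, optimal string alignment — no substring is edited
#' again after a transposition), which is what standard fuzzy-search
#' engines implement and the default used by [fuzzy_search()]; and the
#' unrestricted distance (`method = "dl"`), which additionally satisfies
#' the triangle inequality and is therefore a true metric. The two
#' differ only on rare pairs such as `"ca"`/`"abc"` (OSA 3, unrestricted
#' 2).
#'
#' @param a,b Character scalars (empty strings allowed).
#' @param method `"osa"` (restricted, default) or `"dl"` (unrestricted).
#' @return Non-negative integer distance.
#' @examples
#' dl_distance("ab", "ba")                                    # 1
#' dl_distance("niereninsuffizienz", "nierreninsuffizienz")   # 1
#' @export
dl_distance <- function(a, b, method = c("osa", "dl")) {
  method <- match.arg(method)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (method == "osa") osa_distance(av, bv) else dl_unrestricted(av, bv)
}

osa_distance <- function(av, bv) {
  la <- length(av); lb <- length(bv)
  if (la == 0) return(lb)
  if (lb == 0) return(la)
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- if (av[i] == bv[j]) 0L else 1L
      m <- min(d[i, j + 1] + 1L,      # deletion
               d[i + 1, j] + 1L,      # insertion
               d[i, j] + cost)        # substitution
      if (i > 1 && j > 1 && av[i] == bv[j - 1] && av[i - 1] == bv[j]) {
        m <- min(m, d[i - 1, j - 1] + 1L)  # adjacent transposition
      }
      d[i + 1, j + 1] <- m
    }
  }
  d[la + 1, lb + 1]
}

dl_unrestricted <- function(av, bv) {
  la <- length(av); lb <- length(bv)
  if (la == 0) return(lb)
  if (lb == 0) return(la)
  alphabet <- unique(c(av, bv))
  da <- stats::setNames(rep(0L, length(alphabet)), alphabet)
  maxdist <- la + lb
  # d has an extra border row/col at index 1 holding maxdist
  d <- matrix(0L, la + 2, lb + 2)
  d[1, ] <- maxdist
  d[, 1] <- maxdist
  d[2, 2:(lb + 2)] <- 0:lb
  d[2:(la + 2), 2] <- 0:la
  for (i in seq_len(la)) {
    db <- 0L
    for (j in seq_len(lb)) {
      k <- da[[bv[j]]]  # last row where b[j] occurred in a
      l <- db           # last column matched in this row
      if (av[i] == bv[j]) {
        cost <- 0L
        db <- j
      } else {
        cost <- 1L
      }
      d[i + 2, j + 2] <- min(
        d[i + 1, j + 1] + cost,                      # substitution
        d[i + 2, j + 1] + 1L,                        # insertion
        d[i + 1, j + 2] + 1L,                        # deletion
        d[k + 1, l + 1] + (i - k - 1) + 1 + (j - l - 1)  # transposition
      )
    }
    da[[av[i]]] <- i
  }
  d[la + 2, lb + 2]
}

#' Tokenize free text for term search
#'
#' Case-folded tokens split on Unicode non-letter boundaries; umlauts
#' are preserved and no stemming is applied.
#'
#' @param text Character scalar.
#' @return Character vector of lowercase tokens.
#' @export
tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^\\p{L}]+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Fuzzy search for a term in report text
#'
#' Every token of the case-folded text within the edit-distance budget
#' of the term is returned, so that misspelled variants of a clinical
#' term are still found. With `max_edits = 0` this reduces to exact
#' token search. Staging patterns (e.g. `G1A1` ... `G5A3`) are matched
#' by an exact regular pattern on the raw text instead, because they mix
#' letters and digits.
#'
#' @param text Unicode report text.
#' @param term Search term (non-empty), or a regular expression when
#'   `is_pattern` is `TRUE`.
#' @param max_edits Maximum restricted Damerau-Levenshtein distance.
#' @param is_pattern Match `term` as a case-insensitive regular
#'   expression (distance reported as 0).
#' @return Tibble with `matched_token` and `distance`.
#' @examples
#' fuzzy_search("Nierreninsuffizienz Grad 3", "niereninsuffizienz", 1)
#' @export
fuzzy_search <- function(text, term, max_edits = 1, is_pattern = FALSE) {
  stopifnot(nzchar(term))
  if (is_pattern) {
    m <- regmatches(text, gregexpr(term, text, ignore.case = TRUE, perl = TRUE))[[1]]
    return(tibble(matched_token = tolower(m), distance = rep(0L, length(m))))
  }
  term <- tolower(term)
  toks <- tokenize_text(text)
  if (!length(toks)) return(tibble(matched_token = character(0), distance = integer(0)))
  lens <- nchar(toks)
  cand <- toks[abs(lens - nchar(term)) <= max_edits]
  if (!length(cand)) return(tibble(matched_token = character(0), distance = integer(0)))
  dist <- vapply(cand, function(tok) osa_distance(
    strsplit(tok, "", fixed = TRUE)[[1]],
    strsplit(term, "", fixed = TRUE)[[1]]
  ), integer(1), USE.NAMES = FALSE)
  keep <- dist <= max_edits
  tibble(matched_token = cand[keep], distance = as.integer(dist[keep]))
}

#' Default renal search-term configuration
#'
#' The German-language term list used to audit discharge letters: AKI,
#' CKD, eGFR, KDIGO, kreatinin, niereninsuffizienz, nierenversagen,
#' plus the exact KDIGO staging pattern (G1A1 ... G5A3). Edit-distance
#' budgets follow the common tilde-operator convention: 1 edit for
#' terms up to 8 characters, 2 for longer terms, 0 for the pattern.
#'
#' @return Tibble with columns `term`, `max_edits`, `is_pattern`.
#' @export
default_terms <- function() {
  words <- c("aki", "ckd", "egfr", "kdigo", "kreatinin",
             "niereninsuffizienz", "nierenversagen")
  tibble(
    term = c(words, "G[1-5]A[1-3]"),
    max_edits = c(ifelse(nchar(words) <= 8, 1L, 2L), 0L),
    is_pattern = c(rep(FALSE, length(words)), TRUE)
  )
}

#' @rdname default_terms
#' @param path YAML file with a list of `{term, max_edits, is_pattern}`
#'   entries.
#' @export
read_terms <- function(path) {
  if (!file.exists(path)) stop_config(paste0("terms file not found: ", path))
  y <- yaml::read_yaml(path)
  bind_rows(lapply(y, function(e) tibble(
    term = e$term,
    max_edits = as.integer(e$max_edits %||% 1L),
    is_pattern = isTRUE(e$is_pattern)
  )))
}

#' Scan discharge reports for every search term
#'
#' One hit table per term; each row is one finding of the term in one
#' report, carrying the case ID, report generation date and report
#' type.
#'
#' @param reports Tibble of reports
#'   (`case_id,report_ts,report_type,text`).
#' @param terms Term configuration as from [default_terms()].
#' @param known_cases Optional character vector of valid case IDs;
#'   reports for unknown cases raise a linkage error.
#' @return Named list (by term) of tibbles with columns
#'   `case_id,report_ts,report_type,term,matched_token,distance`.
#' @export
scan_reports <- function(reports, terms = default_terms(), known_cases = NULL) {
  if (!is.null(known_cases)) {
    orphan <- setdiff(reports$case_id, known_cases)
    if (length(orphan)) {
      abort(paste0("report case_id not in cohort: ", paste(orphan, collapse = ", ")),
            class = "renalrules_linkage_error")
    }
  }
  out <- vector("list", nrow(terms))
  names(out) <- terms$term
  for (t in seq_len(nrow(terms))) {
    rows <- list()
    for (r in seq_len(nrow(reports))) {
      hits <- fuzzy_search(reports$text[r], terms$term[t],
                           max_edits = terms$max_edits[t],
                           is_pattern = terms$is_pattern[t])
      if (nrow(hits)) {
        rows[[length(rows) + 1]] <- tibble(
          case_id = reports$case_id[r], report_ts = reports$report_ts[r],
          report_type = reports$report_type[r], term = terms$term[t],
          matched_token = hits$matched_token, distance = hits$distance
        )
      }
    }
    out[[t]] <- if (length(rows)) bind_rows(rows) else
      tibble(case_id = character(0), report_ts = parse_ts(character(0)),
             report_type = character(0), term = character(0),
             matched_token = character(0), distance = integer(0))
  }
  out
}

#' Aggregate term hits and coded diagnoses at case level
#'
#' One row per case with a boolean flag per search term and the case's
#' coded family (`N17`, `N18`, `N17+N18`, `N19` or `none`), the basis
#' for documentation-proportion statistics per code family.
#'
#' @param hits Named list of per-term hit tables from [scan_reports()].
#' @param diagnoses List of `diagnosis_set` objects defining the cases
#'   audited and their codes.
#' @return Tibble with `case_id`, one logical column per term and
#'   `coded_family`.
#' @export
aggregate_cases <- function(hits, diagnoses) {
  case_ids <- vapply(diagnoses, `[[`, character(1), "case_id")
  families <- vapply(diagnoses, function(ds) code_family(ds$icd_codes), character(1))
  audit <- tibble(case_id = case_ids)
  for (term in names(hits)) {
    audit[[term_column(term)]] <- case_ids %in% hits[[term]]$case_id
  }
  audit$coded_family <- families
  audit
}

term_column <- function(term) {
  gsub("[^a-z0-9]+", "_", tolower(term))
}

code_family <- function(codes) {
  has17 <- any(startsWith(codes, "N17"))
  has18 <- any(startsWith(codes, "N18"))
  has19 <- any(startsWith(codes, "N19") | codes == "N19")
  if (has17 && has18) "N17+N18"
  else if (has17) "N17"
  else if (has18) "N18"
  else if (has19) "N19"
  else "none"
}

#' Documentation proportions per coded family
#'
#' For each code family, the share of cases whose discharge letters
#' mention each audited term (two-decimal percentages, half-up).
#'
#' @param case_audit Output of [aggregate_cases()].
#' @return Tibble with one row per coded family, case counts and one
#'   percentage column per term.
#' @export
audit_proportions <- function(case_audit) {
  flag_cols <- setdiff(names(case_audit), c("case_id", "coded_family"))
  case_audit |>
    group_by(.data$coded_family) |>
    summarise(
      n_cases = n(),
      dplyr::across(dplyr::all_of(flag_cols),
                    ~ proportion(sum(.x), dplyr::n()),
                    .names = "pct_{.col}"),
      .groups = "drop"
    )
}
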