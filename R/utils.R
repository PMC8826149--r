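#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

HOURS_PER_DAY <- 24

#' Parse ISO-8601 timestamps to a single UTC timeline
#'
#' All timestamps entering the engines are converted to POSIXct in UTC so
#' that every window rule (48 hours, 7 days, 91 days) reduces to exact
#' arithmetic on fractional hours.
#'
#' @param x Character vector of ISO-8601 timestamps (explicit offsets
#'   honoured; bare dates are taken as midnight UTC).
#' @return POSIXct vector in UTC.
#' @keywords internal
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(x, tz = "UTC"))
  }
  out <- readr::parse_datetime(as.character(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort(sprintf(
      "unparseable timestamp(s): %s",
      paste(utils::head(unique(x[bad]), 5), collapse = ", ")
    ), class = "renalrules_schema_error")
  }
  attr(out, "tzone") <- "UTC"
  out
}

#' Interval between two timestamps in fractional hours
#' @keywords internal
hours_between <- function(earlier, later) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

#' Round half-up at a fixed number of decimals
#'
#' Base `round()` rounds half to even; the reporting tables use the
#' commercial half-up convention, so 0.005 at two decimals becomes 0.01.
#' A tiny epsilon absorbs binary representation error just below .5.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_domain <- function(msg) abort(msg, class = "renalrules_domain_error")
stop_schema <- function(msg) abort(msg, class = "renalrules_schema_error")
stop_ref <- function(msg) abort(msg, class = "renalrules_referential_error")
stop_unit <- function(msg) abort(msg, class = "renalrules_unit_error")
stop_config <- function(msg) abort(msg, class = "renalrules_config_error")
stop_state <- function(msg) abort(msg, class = "renalrules_state_error")
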