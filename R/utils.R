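#' Round half away from zero
#'
#' Count outputs are rounded half-up at the last step only; base `round()`
#' rounds half to even, which would make audit down-adjustment arithmetic
#' depend on parity.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2128.65))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Financial year of a date
#'
#' UK financial years run 1 April to 31 March and are labelled by the
#' starting calendar year, so 2000-03-31 falls in financial year 1999.
#'
#' @param date a `Date` vector.
#' @return integer vector of starting calendar years.
#' @examples
#' financial_year(as.Date(c("2000-03-31", "2000-04-01")))
#' @export
financial_year <- function(date) {
  stopifnot(inherits(date, "Date"))
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y - (m < 4L)
}

# Parse dates under a known format, returning NA (not an error) on failure
# so that callers can quarantine bad rows.
parse_date_quiet <- function(x, format = "%Y-%m-%d") {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & nzchar(x)
  parsed <- as.Date(x[ok], format = format)
  # as.Date() accepts e.g. "2020-02-31" under some formats; round-trip check
  roundtrip <- !is.na(parsed) & format(parsed, format) == x[ok]
  parsed[!roundtrip] <- as.Date(NA)
  out[ok] <- parsed
  out
}

# Uniform random dates in [from, to], inclusive.
random_dates <- function(n, from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  as.Date(sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L,
          origin = from)
}

# Empty-string-safe coalesce to NA
blank_to_na <- function(x) {
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}
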