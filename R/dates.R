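#' Anniversary date arithmetic
#'
#' Adds whole calendar years to a date, keeping the month and day. A
#' February 29 anniversary in a non-leap year rolls forward to March 1
#' (deterministic civil-date convention). All window arithmetic in the
#' package goes through this function so that "one year" means an
#' anniversary year (365 or 366 days), never a fixed 365-day block that
#' would drift over long observation spans.
#'
#' @param dates a `Date` vector.
#' @param k integer number of years to add (may be negative); recycled
#'   against `dates`.
#' @return a `Date` vector.
#' @examples
#' add_anniversary_years(as.Date("2005-03-10"), 1)
#' add_anniversary_years(as.Date("2004-02-29"), 1)  # rolls to 2005-03-01
#' @export
add_anniversary_years <- function(dates, k) {
  stopifnot(inherits(dates, "Date"), all(k == round(k)))
  if (length(dates) == 0L || length(k) == 0L)
    return(as.Date(character(0)))
  n <- max(length(dates), length(k))
  dates <- rep_len(dates, n)
  k <- rep_len(as.integer(k), n)
  lt <- as.POSIXlt(dates)
  y <- lt$year + 1900L + k
  out <- as.Date(sprintf("%04d-%02d-%02d", y, lt$mon + 1L, lt$mday),
                 format = "%Y-%m-%d")
  bad <- is.na(out) & !is.na(dates)
  if (any(bad)) out[bad] <- as.Date(sprintf("%04d-03-01", y[bad]))
  out
}

# Half-open [start, end) membership at day granularity.
in_window <- function(dates, window) {
  dates >= window[1L] & dates < window[2L]
}

as_window <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop("window must satisfy start < end", call. = FALSE)
  c(start, end)
}
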