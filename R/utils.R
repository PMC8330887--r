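# Shared helpers: journal-style rounding and ISO-week bookkeeping.

# round() in R rounds half to even; published percentage tables round half up.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' ISO week key for a timestamp
#'
#' Weeks run Monday to Sunday (ISO 8601); the key is `"<iso year>-W<ww>"`,
#' zero-padded so keys sort lexicographically within and across years.
#'
#' @param x Date or POSIXct vector.
#' @return Character vector of week keys such as `"2020-W13"`.
#' @export
#' @examples
#' iso_week_key(as.Date("2020-03-23"))
iso_week_key <- function(x) {
  d <- lubridate::as_date(x)
  sprintf("%d-W%02d", lubridate::isoyear(d), lubridate::isoweek(d))
}

#' Monday of the ISO week containing a timestamp
#'
#' @param x Date or POSIXct vector.
#' @return Date vector of week-start Mondays.
#' @export
week_monday <- function(x) {
  lubridate::floor_date(lubridate::as_date(x), unit = "week", week_start = 1)
}
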