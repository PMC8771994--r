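#' Parse a 24-h clock time to decimal hours
#'
#' Clock times in the input workbook use the 24-hour `HH:MM` format; all
#' internal computation is in decimal hours.
#'
#' @param x character vector of `HH:MM` times.
#' @return numeric vector of hours since midnight; `NA` where unparseable.
#' @examples
#' parse_clock("08:30")  # 8.5
#' @export
parse_clock <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", trimws(as.character(x)))
  if (any(ok)) {
    parts <- strsplit(trimws(as.character(x[ok])), ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60, 0)
  }
  out
}

#' Format decimal hours as a 24-h clock time
#'
#' Minutes are rounded half-up; times wrap at 24 h so a route returning
#' after midnight prints the clock time of the following day.
#'
#' @param hours numeric vector of hours since midnight.
#' @return character vector in `HH:MM` format.
#' @export
format_clock <- function(hours) {
  mins <- floor(hours * 60 + 0.5)
  mins <- mins %% (24 * 60)
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}
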