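#' Day-indexed series
#'
#' A `daily_series` is a contiguous day-of-year-indexed vector of real values
#' (fish counts, discharge, temperature) for a single year. Day-of-year is
#' 1-based (Jan 1 = day 1) and a season never wraps a year boundary.
#'
#' @param values numeric vector, one value per day.
#' @param first_day day-of-year of the first value.
#' @param year calendar year the series belongs to.
#' @return An object of class `daily_series`: a numeric vector with
#'   attributes `first_day` and `year`.
#' @examples
#' s <- daily_series(c(0, 5, 12, 5, 0), first_day = 250, year = 2000)
#' days(s)
#' sum(s)
#' @export
daily_series <- function(values, first_day, year = NA_integer_) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  first_day <- as.integer(first_day)
  if (is.na(first_day) || first_day < 1L)
    stop("'first_day' must be a positive day-of-year")
  if (first_day + length(values) - 1L > 366L)
    stop("daily series must not wrap past the year boundary (day 366)")
  if (anyNA(values)) stop("daily series values must not contain NA")
  structure(as.numeric(values),
            first_day = first_day,
            year = as.integer(year),
            class = "daily_series")
}

#' @rdname daily_series
#' @param x a `daily_series`.
#' @export
days <- function(x) {
  fd <- attr(x, "first_day")
  seq.int(fd, fd + length(x) - 1L)
}

#' @export
print.daily_series <- function(x, ...) {
  d <- days(x)
  cat(sprintf("<daily_series> year %s, days %d-%d (%d days), total %.6g\n",
              attr(x, "year"), d[1L], d[length(d)], length(x),
              sum(unclass(x))))
  invisible(x)
}

#' @export
as.data.frame.daily_series <- function(x, ...) {
  data.frame(year = attr(x, "year"), day = days(x), value = as.numeric(x))
}

# internal: subset/extend a daily series onto a wider day window, zero-filled
.window_series <- function(x, first_day, last_day) {
  d <- days(x)
  out <- numeric(last_day - first_day + 1L)
  keep <- d >= first_day & d <= last_day
  out[d[keep] - first_day + 1L] <- as.numeric(x)[keep]
  daily_series(out, first_day, attr(x, "year"))
}
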