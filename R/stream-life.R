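#' Stream-life schedule
#'
#' In-river life span of adult sockeye links live-count surveys to daily
#' entries. Early-arriving fish live longer than late arrivals, and average
#' stream-life may also decline across years. A schedule holds the life span
#' (days) of the earliest cohort (`initial`), of the latest cohort (`final`),
#' and a between-year trend expressed as the total change in days across the
#' study period. Within a year the cohort life span is interpolated linearly
#' between `initial` at the first day of the season window and `final` at the
#' last; the constant case `initial == final` reduces to the classic fixed
#' stream-life accounting model.
#'
#' @param initial days lived by the earliest-entering cohort.
#' @param final days lived by the latest-entering cohort (`final <= initial`).
#' @param trend total change in stream-life (days) from the first to the last
#'   year of the study period; applied to `initial` and `final` jointly and
#'   clamped so every cohort lives at least 1 day. Negative = decline.
#' @return An object of class `stream_life_schedule`.
#' @examples
#' stream_life_schedule(15)            # fixed 15-day stream-life
#' sl <- stream_life_schedule(18, 11, trend = -2)
#' mean(sl)                            # mid-season, mid-period average
#' @export
stream_life_schedule <- function(initial, final = initial, trend = 0) {
  stopifnot(is.numeric(initial), length(initial) == 1L, is.finite(initial),
            is.numeric(final), length(final) == 1L, is.finite(final),
            is.numeric(trend), length(trend) == 1L, is.finite(trend))
  if (initial < 1) stop("'initial' stream-life must be at least 1 day")
  if (final > initial) stop("'final' stream-life must not exceed 'initial'")
  if (final < 1) stop("'final' stream-life must be at least 1 day")
  structure(list(initial = initial, final = final, trend = trend),
            class = "stream_life_schedule")
}

#' @export
print.stream_life_schedule <- function(x, ...) {
  cat(sprintf(
    "<stream_life_schedule> initial %.3g d, final %.3g d, between-year trend %+.3g d\n",
    x$initial, x$final, x$trend))
  invisible(x)
}

#' @describeIn stream_life_schedule mean of the initial and final cohort
#'   life spans (the season-average stream-life at mid study period).
#' @param x a `stream_life_schedule`.
#' @param ... ignored.
#' @export
mean.stream_life_schedule <- function(x, ...) (x$initial + x$final) / 2

# internal: integer life span for each day of a window.
# year_frac in [0, 1] locates the year within the study period for the
# between-year trend; the within-year decline is anchored on the window ends.
.cohort_lifespans <- function(schedule, first_day, last_day, year_frac = 0) {
  stopifnot(inherits(schedule, "stream_life_schedule"))
  ini <- schedule$initial + schedule$trend * year_frac
  fin <- schedule$final + schedule$trend * year_frac
  n <- last_day - first_day + 1L
  if (n == 1L) L <- ini else
    L <- ini + (fin - ini) * (seq_len(n) - 1L) / (n - 1L)
  pmax(1L, as.integer(round(L)))
}
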