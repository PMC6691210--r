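#' Seasonal temperature statistics
#'
#' Seasonal means over calendar windows (spring: March-May, summer:
#' June-August, autumn: September-November) and the annual maximum.
#' Sub-monthly observations are averaged by month first, so that unevenly
#' sampled months do not dominate a seasonal mean; the seasonal mean is then
#' the mean of its monthly means. An empty season yields `NA`, never zero.
#'
#' @param temp either a [daily_series] of temperatures, or a data frame with
#'   columns `day` (day-of-year) and `value` (possibly sparse).
#' @return named numeric vector: `spring`, `summer`, `autumn`, `annual_max`.
#' @examples
#' seasonal_stats(daily_series(rep(10, 365), 1))
#' @export
seasonal_stats <- function(temp) {
  if (inherits(temp, "daily_series")) {
    df <- data.frame(day = days(temp), value = as.numeric(temp))
  } else {
    stopifnot(is.data.frame(temp), all(c("day", "value") %in% names(temp)))
    df <- temp[stats::complete.cases(temp[, c("day", "value")]), ]
  }
  month <- .month_of_doy(df$day)
  monthly <- tapply(df$value, month, mean)
  season_mean <- function(months) {
    m <- monthly[names(monthly) %in% as.character(months)]
    if (!length(m)) NA_real_ else mean(m)
  }
  c(spring = season_mean(3:5),
    summer = season_mean(6:8),
    autumn = season_mean(9:11),
    annual_max = if (nrow(df)) max(df$value) else NA_real_)
}

# month of a 1-based day-of-year (non-leap calendar)
.month_of_doy <- function(day) {
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(day - 1L, c(0, ends[-12L])) # 1..12
}

# first day-of-year of each month (non-leap)
.month_starts <- function() c(1, cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))[1:11] + 1)

#' Monthly means of a sparse series
#'
#' @param day day-of-year of each observation.
#' @param value observed values.
#' @param months months to report (integer 1-12).
#' @return named numeric vector of monthly means (NA when a month has no
#'   observations).
#' @export
monthly_means <- function(day, value, months = 1:12) {
  m <- .month_of_doy(day)
  out <- vapply(months, function(mm) {
    v <- value[m == mm]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  names(out) <- month.abb[months]
  out
}

#' River-flow covariates of spawning timing
#'
#' Three discharge metrics used as candidate predictors of spawning
#' phenology: (a) mean discharge over the months when most spawning occurs
#' (September-November); (b) the extent of early-spawning-season high-flow
#' events, counted as days between 1 August and 30 September with discharge
#' strictly above the long-term 75th percentile; and (c) the cumulative
#' discharge increase during September, the sum of all positive day-to-day
#' differences in flow (a freshet measure).
#'
#' @param discharge a [daily_series] of daily discharge covering at least
#'   1 August - 30 November (days 213-334).
#' @param long_term_p75 the long-term 75th-percentile threshold for metric
#'   (b); see [flow_threshold()].
#' @return named numeric vector: `mean_sep_nov`, `highflow_days`,
#'   `sep_cum_increase`.
#' @examples
#' q <- daily_series(rep(10, 365), 1)
#' flow_metrics(q, long_term_p75 = 12)
#' @export
flow_metrics <- function(discharge, long_term_p75) {
  stopifnot(inherits(discharge, "daily_series"),
            is.numeric(long_term_p75), length(long_term_p75) == 1L)
  d <- days(discharge)
  need <- 213:334 # Aug 1 - Nov 30
  missing_days <- setdiff(need, d)
  if (length(missing_days))
    stop("discharge series is missing required days: ",
         paste(utils::head(missing_days, 10L), collapse = ", "),
         if (length(missing_days) > 10L) ", ...")
  v <- as.numeric(discharge)
  at <- function(dd) v[match(dd, d)]
  sep_nov <- at(244:334)          # Sep 1 - Nov 30
  augsep <- at(213:273)           # Aug 1 - Sep 30
  sep <- at(244:273)              # September
  sep_prev <- at(243:272)         # day-before values for the differences
  c(mean_sep_nov = mean(sep_nov),
    highflow_days = sum(augsep > long_term_p75),
    sep_cum_increase = sum(pmax(0, sep - sep_prev)))
}

#' Long-term 75th-percentile flow threshold
#'
#' The high-flow-day metric needs a single long-term threshold. It is
#' computed once per dataset over all years' 1 August - 30 September daily
#' flows (the same calendar window the metric counts over, avoiding
#' winter-flow contamination).
#'
#' @param env_daily data frame with columns `year`, `day`, `discharge_cms`.
#' @return the 75th percentile (type 7) of Aug-Sep daily discharge.
#' @export
flow_threshold <- function(env_daily) {
  stopifnot(all(c("day", "discharge_cms") %in% names(env_daily)))
  q <- env_daily$discharge_cms[env_daily$day >= 213 & env_daily$day <= 273]
  if (!length(q)) stop("no August-September flows available for the threshold")
  stats::quantile(q, 0.75, names = FALSE, na.rm = TRUE)
}

#' Build the covariate table from daily environmental series
#'
#' Computes, per year, the seasonal temperature means and annual maximum,
#' and the three flow metrics (with the long-term 75th-percentile threshold
#' fixed once over the whole dataset). The freshet covariate `E1` enters
#' trend models as `log(sep_cum_increase + 1)` (the +1 guards zero years);
#' the autumn temperature mean is `E2`.
#'
#' @param env_daily data frame with columns `year`, `day`, `discharge_cms`,
#'   `temp_c`.
#' @return data frame with one row per year: `year`, temperature statistics,
#'   flow metrics, and `E1`, `E2`.
#' @examples
#' sc <- scenario_config(years = 2000:2002)
#' scn <- simulate_scenario(sc)
#' head(build_covariates(scn$env_daily))
#' @export
build_covariates <- function(env_daily) {
  stopifnot(is.data.frame(env_daily),
            all(c("year", "day", "discharge_cms", "temp_c") %in% names(env_daily)))
  thr <- flow_threshold(env_daily)
  years <- sort(unique(env_daily$year))
  rows <- lapply(years, function(y) {
    e <- env_daily[env_daily$year == y, ]
    ts <- seasonal_stats(data.frame(day = e$day, value = e$temp_c))
    q <- daily_series(e$discharge_cms[order(e$day)], min(e$day), y)
    fm <- flow_metrics(q, thr)
    data.frame(year = y, t(ts), t(fm))
  })
  out <- do.call(rbind, rows)
  out$E1 <- log(out$sep_cum_increase + 1)
  out$E2 <- out$autumn
  rownames(out) <- NULL
  out
}
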