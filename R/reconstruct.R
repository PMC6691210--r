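#' Interpolate sparse survey counts to a daily series
#'
#' Live-fish surveys are conducted every few days; timing analyses need daily
#' abundance. Counts are linearly interpolated between consecutive surveys,
#' and the run is assumed absent outside the observed window: the day before
#' the first survey and the day after the last are set to zero so that the
#' interpolated series rises from and returns to zero.
#'
#' Years with fewer than three surveys are considered unreliable and are
#' rejected (the analysis drops such years rather than imputing them).
#'
#' @param surveys data frame with columns `day` (day-of-year, strictly
#'   increasing) and `live_count` (non-negative), and optionally `year`.
#' @return A [daily_series] of interpolated daily live counts spanning from
#'   the day before the first survey to the day after the last.
#' @examples
#' s <- data.frame(day = c(250, 255, 262), live_count = c(0, 80, 10))
#' interpolate_daily(s)
#' @export
interpolate_daily <- function(surveys) {
  stopifnot(is.data.frame(surveys), all(c("day", "live_count") %in% names(surveys)))
  day <- as.numeric(surveys$day)
  cnt <- as.numeric(surveys$live_count)
  if (anyNA(day) || anyNA(cnt)) stop("surveys contain missing values")
  if (nrow(surveys) < 3L)
    stop("fewer than 3 surveys in year; too few to be reliable - year excluded")
  if (any(diff(day) <= 0)) stop("survey days must be strictly increasing")
  if (any(cnt < 0)) stop("live counts must be non-negative")
  year <- if ("year" %in% names(surveys)) surveys$year[1L] else NA_integer_
  d0 <- day[1L] - 1L
  d1 <- day[length(day)] + 1L
  if (d0 < 1L) { # season starts at day 1: no room for the leading zero
    d0 <- 1L
  }
  grid <- seq.int(d0, d1)
  vals <- stats::approx(x = c(d0, day, d1), y = c(0, cnt, 0), xout = grid,
                        method = "linear", ties = "ordered")$y
  daily_series(pmax(0, vals), first_day = d0, year = year)
}

#' Reconstruct daily river entries from daily live counts
#'
#' Inverts the survey accounting model: each day's deaths are the entrants of
#' the cohort whose stream-life expires that day, and new entries are the
#' day-to-day change in live fish plus deaths,
#' `entering[t] = live[t] - live[t-1] + deaths[t]`, with
#' `deaths[t] = entering[t - L]` for constant stream-life `L`. The recursion
#' is evaluated left to right with entries and live counts identically zero
#' before the first day. Observation error in the surveys and process error in
#' true stream-life can make individual reconstructed entries negative; they
#' are retained (not truncated) because the downstream cumulative-normal fit
#' is designed to absorb these oscillations.
#'
#' @param live a [daily_series] of daily live counts (e.g. from
#'   [interpolate_daily()]).
#' @param schedule a [stream_life_schedule]; cohort life spans are
#'   interpolated across the live-count window.
#' @param year_frac position of the year within the study period in `[0, 1]`,
#'   used by the schedule's between-year trend. Default 0 (first year /
#'   no trend).
#' @param anchor optional `c(first_day, last_day)` window on which the
#'   within-year stream-life decline is anchored (e.g. the entry season);
#'   defaults to the live-count window. Irrelevant for constant schedules.
#' @return A [daily_series] of reconstructed daily entries (may contain
#'   negative values).
#' @examples
#' live <- daily_series(c(10, 16, 12, 4, 0), first_day = 1)
#' reconstruct_entries(live, stream_life_schedule(2))
#' @export
reconstruct_entries <- function(live, schedule = stream_life_schedule(15),
                                year_frac = 0, anchor = NULL) {
  stopifnot(inherits(live, "daily_series"))
  d <- days(live)
  if (is.null(anchor)) anchor <- c(d[1L], d[length(d)])
  # life spans on the anchor window, then evaluated at the live-window days
  # (extrapolated flat outside the anchor)
  La <- .cohort_lifespans(schedule, anchor[1L], anchor[2L], year_frac)
  L <- La[pmin(pmax(d - anchor[1L] + 1L, 1L), length(La))]
  ent <- .reconstruct_core(as.numeric(live), L)
  daily_series(ent, first_day = attr(live, "first_day"),
               year = attr(live, "year"))
}

# internal: the accounting recursion on bare vectors (used per Monte Carlo
# draw, so kept allocation-light). L is the integer life span per day index.
.reconstruct_core <- function(live, L) {
  n <- length(live)
  ent <- numeric(n)
  deaths <- numeric(n + max(L) + 1L)
  prev <- 0
  for (t in seq_len(n)) {
    e <- live[t] - prev + deaths[t]
    ent[t] <- e
    dd <- t + L[t]
    if (dd <= length(deaths)) deaths[dd] <- deaths[dd] + e
    prev <- live[t]
  }
  ent
}

#' Fit a cumulative-normal distribution to reconstructed entries
#'
#' The raw deaths/entries recursion can oscillate (and go negative) under
#' observation error. Descriptive statistics of entry timing are therefore
#' taken from a cumulative normal distribution fitted to the cumulative
#' distribution of reconstructed entries by ordinary least squares on
#' cumulative *proportions* (scale-free, so years of different run size are
#' comparable): minimise `sum_t (Phi((t - mu)/sigma) - C_t)^2`.
#'
#' A half-day continuity correction is applied internally (the cumulative
#' proportion *through* day `t` is compared with the normal CDF at `t + 1/2`)
#' so that the fit is exactly self-consistent with integer-day binning and
#' `mu` is unbiased. Optimisation is a damped Gauss-Newton iteration with an
#' analytic Jacobian, started from the empirical median and interquartile
#' range, with jittered restarts and a Nelder-Mead fallback.
#'
#' @param entries a [daily_series] of (possibly negative) daily entries.
#' @param sigma_min lower bound for `sigma` (days); a point-mass input pins
#'   `sigma` at this bound.
#' @return list with components `mu`, `sigma`, `sse` (the OLS objective at
#'   the optimum), and `converged`.
#' @examples
#' e <- daily_series(c(1, 4, 10, 4, 1), first_day = 270)
#' fit_entry_cdf(e)
#' @export
fit_entry_cdf <- function(entries, sigma_min = 0.01) {
  stopifnot(inherits(entries, "daily_series"))
  tot <- sum(as.numeric(entries))
  if (!is.finite(tot) || tot <= 0)
    stop("total of reconstructed entries must be positive to fit entry timing")
  d <- days(entries)
  cp <- cumsum(as.numeric(entries)) / tot
  .fit_cdf_core(d + 0.5, cp, sigma_min = sigma_min)
}

# internal: least-squares fit of pnorm((x - mu)/sigma) to p at abscissae x.
# thorough = FALSE does a single damped Gauss-Newton pass from the quantile
# start (used inside Monte Carlo loops, where the start is always good).
.fit_cdf_core <- function(x, p, sigma_min = 0.01, thorough = TRUE) {
  # initial values: first abscissa where cumulative proportion exceeds 0.5;
  # sigma from the 25-75% spread scaled to a normal IQR
  q_at <- function(q) {
    i <- which(p > q)
    if (length(i)) x[i[1L]] else x[length(x)]
  }
  mu0 <- q_at(0.5)
  s0 <- max((q_at(0.75) - q_at(0.25)) / 1.349, sigma_min)
  sse <- function(mu, s) sum((stats::pnorm((x - mu) / s) - p)^2)

  gauss_newton <- function(mu, s) {
    lambda <- 1e-3
    f <- sse(mu, s)
    for (it in 1:60) {
      z <- (x - mu) / s
      phi <- stats::dnorm(z)
      r <- stats::pnorm(z) - p
      j1 <- -phi / s          # d residual / d mu
      j2 <- -z * phi / s      # d residual / d sigma
      g1 <- sum(r * j1); g2 <- sum(r * j2)
      a11 <- sum(j1 * j1) + lambda; a22 <- sum(j2 * j2) + lambda
      a12 <- sum(j1 * j2)
      det <- a11 * a22 - a12 * a12
      if (!is.finite(det) || det <= 0) break
      dmu <- -( a22 * g1 - a12 * g2) / det
      ds  <- -(-a12 * g1 + a11 * g2) / det
      mu_new <- mu + dmu
      s_new <- max(s + ds, sigma_min)
      f_new <- sse(mu_new, s_new)
      if (is.finite(f_new) && f_new <= f) {
        conv <- abs(mu_new - mu) < 1e-8 && abs(s_new - s) < 1e-8
        mu <- mu_new; s <- s_new; f <- f_new
        lambda <- max(lambda / 4, 1e-9)
        if (conv) break
      } else {
        lambda <- lambda * 8
        if (lambda > 1e6) break
      }
    }
    list(mu = mu, sigma = s, sse = f)
  }

  best <- gauss_newton(mu0, s0)
  # jittered restarts, then Nelder-Mead, if the first pass looks poor
  if (thorough && best$sse > 1e-10) {
    for (k in 1:3) {
      cand <- gauss_newton(mu0 + c(-2, 2, 5)[k], s0 * c(0.5, 2, 1)[k])
      if (cand$sse < best$sse) best <- cand
    }
    nm <- stats::optim(c(best$mu, log(best$sigma)),
                       function(th) sse(th[1L], max(exp(th[2L]), sigma_min)),
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))
    if (is.finite(nm$value) && nm$value < best$sse)
      best <- list(mu = nm$par[1L],
                   sigma = max(exp(nm$par[2L]), sigma_min),
                   sse = nm$value)
  }
  if (!is.finite(best$sse))
    stop("entry CDF fit failed to converge; best iterate mu=", best$mu,
         " sigma=", best$sigma)
  list(mu = best$mu, sigma = best$sigma, sse = best$sse, converged = TRUE)
}

#' Shift an entry distribution to a spawning distribution
#'
#' Fish hold in the river for several days between entry and completion of
#' spawning; the spawning distribution is the entry distribution offset by
#' that average delay (shape unchanged): `mu_spawn = mu_entry + delay`.
#'
#' @param mu_entry mean entry day (day-of-year).
#' @param delay average days between river entry and completed spawning
#'   (0-30; tagging studies suggest slightly more than one week, point
#'   estimate 8 d).
#' @return mean spawning day (day-of-year).
#' @examples
#' spawning_mean(280, delay = 8)  # 288
#' @export
spawning_mean <- function(mu_entry, delay = 8) {
  stopifnot(is.numeric(delay), all(delay >= 0), all(delay <= 30))
  mu_entry + delay
}

#' Percentile completion dates of a daily series
#'
#' For each requested completion fraction `p`, returns the first day on which
#' the cumulative total *strictly* exceeds `p` of the annual total; the run
#' duration is the span between the 90% and 10% dates. These are the standard
#' run-timing reference points (the 50% date is the median timing).
#'
#' @param x a [daily_series] (or a numeric vector of daily values with
#'   `first_day`).
#' @param percentiles completion fractions in (0, 1).
#' @param first_day day-of-year of the first value when `x` is a bare vector.
#' @return An object of class `timing_summary`: a named list with the
#'   percentile dates (`d10`, `d25`, ... named by percentage), `duration`
#'   (`d90 - d10` when both requested), and `year`.
#' @examples
#' timing_percentiles(daily_series(c(1, 2, 3, 4), 1))  # median on day 3
#' @export
timing_percentiles <- function(x, percentiles = c(0.10, 0.25, 0.50, 0.75, 0.90),
                               first_day = NULL) {
  if (!inherits(x, "daily_series")) {
    stopifnot(!is.null(first_day))
    x <- daily_series(x, first_day)
  }
  stopifnot(all(percentiles > 0), all(percentiles < 1),
            !is.unsorted(percentiles))
  tot <- sum(as.numeric(x))
  if (!is.finite(tot) || tot <= 0)
    stop("percentile dates undefined: series total is not positive")
  cp <- cumsum(as.numeric(x)) / tot
  d <- days(x)
  dates <- vapply(percentiles, function(p) {
    i <- which(cp > p)
    as.numeric(if (length(i)) d[i[1L]] else d[length(d)])
  }, numeric(1))
  names(dates) <- sprintf("d%d", round(100 * percentiles))
  dur <- if (all(c("d10", "d90") %in% names(dates)))
    unname(dates["d90"] - dates["d10"]) else NA_real_
  structure(list(year = attr(x, "year"), dates = dates, duration = dur),
            class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  cat("<timing_summary>", if (!is.na(x$year)) paste0("year ", x$year), "\n")
  print(x$dates)
  if (!is.na(x$duration)) cat(sprintf("duration (d90 - d10): %g days\n", x$duration))
  invisible(x)
}
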