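#' Fit a river-entry timing model to live-count surveys
#'
#' The central model of the package. From sparse surveys of live adult salmon
#' in one year, `run_timing()` (i) linearly interpolates the counts to a
#' daily series, (ii) inverts the stream-life accounting model to reconstruct
#' daily river entries (see [reconstruct_entries()]), and (iii) stabilises the
#' reconstruction by fitting a cumulative normal distribution to the
#' cumulative entry proportions by least squares (see [fit_entry_cdf()]).
#' The spawning distribution is the entry distribution offset by the average
#' entry-to-spawning delay.
#'
#' @param surveys data frame of one year's surveys with columns `day`
#'   (day-of-year) and `live_count`; alternatively a [daily_series] of daily
#'   live counts may be passed via `live` instead.
#' @param stream_life a [stream_life_schedule].
#' @param spawning_delay days between river entry and completed spawning.
#' @param year_frac position of the year in the study period (`[0, 1]`) for
#'   the schedule's between-year trend.
#' @param live optional [daily_series] of daily live counts, bypassing
#'   interpolation (e.g. when daily counts are already available).
#' @param anchor optional `c(first_day, last_day)` anchor window for the
#'   within-year stream-life decline; see [reconstruct_entries()].
#' @return An object of class `run_timing` with components `mu_entry`,
#'   `sigma`, `mu_spawn`, `sse`, `total_entries`, `entries` (raw
#'   reconstructed daily entries), `live` (daily live counts), `surveys`,
#'   `stream_life`, `spawning_delay`, `year`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `simulate()` and `plot()`.
#' @examples
#' set.seed(1)
#' sc <- scenario_config(years = 2000, run_size = 5000, survey_cv = 0)
#' run <- generate_run(sc, 2000)
#' fit <- run_timing(run$surveys, stream_life = sc$stream_life)
#' coef(fit)
#' summary(fit)
#' @export
run_timing <- function(surveys = NULL, stream_life = stream_life_schedule(15),
                       spawning_delay = 8, year_frac = 0, live = NULL,
                       anchor = NULL) {
  if (is.null(live)) {
    stopifnot(is.data.frame(surveys))
    live <- interpolate_daily(surveys)
  } else {
    stopifnot(inherits(live, "daily_series"))
  }
  entries <- reconstruct_entries(live, stream_life, year_frac, anchor)
  fit <- fit_entry_cdf(entries)
  structure(list(
    mu_entry = fit$mu,
    sigma = fit$sigma,
    mu_spawn = spawning_mean(fit$mu, spawning_delay),
    sse = fit$sse,
    total_entries = sum(as.numeric(entries)),
    entries = entries,
    live = live,
    surveys = surveys,
    stream_life = stream_life,
    spawning_delay = spawning_delay,
    year = attr(live, "year")
  ), class = "run_timing")
}

#' @export
print.run_timing <- function(x, ...) {
  cat("River-entry timing model (cumulative-normal fit)\n")
  if (!is.na(x$year)) cat("Year:", x$year, "\n")
  cat(sprintf("  entry mean (mu):   day %.2f\n", x$mu_entry))
  cat(sprintf("  entry SD (sigma):  %.2f days\n", x$sigma))
  cat(sprintf("  spawning mean:     day %.2f (delay %g d)\n",
              x$mu_spawn, x$spawning_delay))
  cat(sprintf("  reconstructed run: %.4g fish; fit SSE %.3g\n",
              x$total_entries, x$sse))
  invisible(x)
}

#' @export
coef.run_timing <- function(object, ...) {
  c(mu_entry = object$mu_entry, sigma = object$sigma,
    mu_spawn = object$mu_spawn)
}

#' @export
summary.run_timing <- function(object, ...) {
  pct_entries <- timing_percentiles(.nonneg_series(object$entries))
  structure(list(fit = object, percentiles = pct_entries),
            class = "summary.run_timing")
}

#' @export
print.summary.run_timing <- function(x, ...) {
  print(x$fit)
  cat("Entry completion dates (from reconstructed entries, negatives zeroed):\n")
  print(x$percentiles$dates)
  cat(sprintf("  duration (d90 - d10): %g days\n", x$percentiles$duration))
  invisible(x)
}

# reconstructed entries with negatives zeroed, for descriptive percentiles
.nonneg_series <- function(x) {
  daily_series(pmax(0, as.numeric(x)), attr(x, "first_day"), attr(x, "year"))
}

#' Predict from a fitted run-timing model
#'
#' @param object a [run_timing] fit.
#' @param newdata numeric vector of days-of-year (defaults to the fitted
#'   window).
#' @param type `"cdf"` for the cumulative entry proportion at end of day,
#'   `"density"` for the expected daily entry proportion, `"entries"` for the
#'   expected daily entry count (density times the reconstructed total), or
#'   `"spawn_cdf"` for the cumulative spawning proportion.
#' @param ... ignored.
#' @export
predict.run_timing <- function(object, newdata = NULL,
                               type = c("cdf", "density", "entries", "spawn_cdf"),
                               ...) {
  type <- match.arg(type)
  d <- if (is.null(newdata)) days(object$entries) else as.numeric(newdata)
  switch(type,
    cdf = stats::pnorm(d + 0.5, object$mu_entry, object$sigma),
    spawn_cdf = stats::pnorm(d + 0.5, object$mu_spawn, object$sigma),
    density = stats::pnorm(d + 0.5, object$mu_entry, object$sigma) -
              stats::pnorm(d - 0.5, object$mu_entry, object$sigma),
    entries = (stats::pnorm(d + 0.5, object$mu_entry, object$sigma) -
               stats::pnorm(d - 0.5, object$mu_entry, object$sigma)) *
              object$total_entries)
}

#' @export
fitted.run_timing <- function(object, ...) {
  predict(object, type = "cdf")
}

#' @export
residuals.run_timing <- function(object, ...) {
  cp <- cumsum(as.numeric(object$entries)) / object$total_entries
  cp - fitted(object)
}

#' Simulate entry dates from a fitted run-timing model
#'
#' Draws integer entry days from the fitted normal entry distribution
#' (rounded to the day grid), `nsim` replicates of the reconstructed run
#' size.
#'
#' @param object a [run_timing] fit.
#' @param nsim number of replicate date vectors.
#' @param seed optional seed, as for [stats::simulate()].
#' @param ... ignored.
#' @export
simulate.run_timing <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(1L, round(object$total_entries))
  replicate(nsim,
            as.integer(round(stats::rnorm(n, object$mu_entry, object$sigma))),
            simplify = FALSE)
}

#' @export
plot.run_timing <- function(x, ...) {
  d <- days(x$live)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(d, as.numeric(x$live), type = "l", xlab = "day of year",
                 ylab = "live fish", main = "Interpolated live counts", ...)
  if (is.data.frame(x$surveys))
    graphics::points(x$surveys$day, x$surveys$live_count, pch = 16)
  de <- days(x$entries)
  graphics::plot(de, as.numeric(x$entries), type = "h", xlab = "day of year",
                 ylab = "entries / day",
                 main = sprintf("Reconstructed entries and fitted N(%.1f, %.1f)",
                                x$mu_entry, x$sigma))
  graphics::lines(de, predict(x, de, type = "entries"), col = 2, lwd = 2)
  invisible(x)
}
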