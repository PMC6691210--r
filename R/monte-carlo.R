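#' Monte Carlo parameter ranges for the selection model
#'
#' Broad uniform ranges intended to encompass all plausible values of the
#' uncertain reconstruction and selection parameters: initial stream-life
#' 14-22 d, final stream-life 50-100% of the drawn initial, between-year
#' stream-life trend -4 to 0 d, spawning delay 5-11 d, hatchery survival
#' advantage 0.6-0.95. `mc_point_estimates()` gives the corresponding best
#' point estimates (18 d, 11 d i.e. fraction 11/18, -2 d, 8 d, 0.83).
#'
#' @param point collapse every range to its point estimate (degenerate
#'   uniforms), so each Monte Carlo draw reproduces the deterministic
#'   pipeline value.
#' @return named list of `c(lo, hi)` ranges: `initial`, `final_frac`,
#'   `trend`, `delay`, `advantage`.
#' @export
mc_ranges <- function(point = FALSE) {
  if (point) {
    pe <- mc_point_estimates()
    return(lapply(pe, function(v) c(v, v)))
  }
  list(initial = c(14, 22), final_frac = c(0.5, 1.0), trend = c(-4, 0),
       delay = c(5, 11), advantage = c(0.6, 0.95))
}

#' @rdname mc_ranges
#' @export
mc_point_estimates <- function() {
  list(initial = 18, final_frac = 11 / 18, trend = -2, delay = 8,
       advantage = 0.83)
}

#' Assemble selection-model inputs
#'
#' Extracts from a simulated scenario (or equivalent raw tables) the fixed
#' data the selection chain needs: daily live-count series per year (from
#' surveys via [interpolate_daily()] when daily counts are not already
#' available), egg-weighted hatchery spawn means, and the proportion of each
#' return spawned in the hatchery.
#'
#' @param x a `run_scenario` from [simulate_scenario()], or a list with
#'   `surveys`, `egg_take` and a `p_hatchery` table
#'   (`year`, `p_hatchery`).
#' @param final_year last observed return year (defaults to the last year
#'   present).
#' @return list with `years`, `live` (list of [daily_series]),
#'   `hatchery_mean`, `p_hatchery` (vectors aligned with `years`), and
#'   `final_year`. Years without hatchery take carry `NA` means.
#' @export
selection_inputs <- function(x, final_year = NULL) {
  if (inherits(x, "run_scenario")) {
    surveys <- x$surveys; egg_take <- x$egg_take
    ph <- x$ground_truth[, c("year", "p_hatchery")]
  } else {
    surveys <- x$surveys; egg_take <- x$egg_take
    ph <- x$p_hatchery
  }
  years <- sort(unique(surveys$year))
  live <- lapply(years, function(y) {
    interpolate_daily(surveys[surveys$year == y, , drop = FALSE])
  })
  names(live) <- years
  hm <- hatchery_spawn_means(egg_take)
  hatchery_mean <- hm$hatchery_mean[match(years, hm$year)]
  p_h <- ph$p_hatchery[match(years, ph$year)]
  p_h[is.na(p_h)] <- 0
  if (is.null(final_year)) final_year <- max(years)
  list(years = years, live = live, hatchery_mean = hatchery_mean,
       p_hatchery = p_h, final_year = final_year)
}

#' Monte Carlo sensitivity analysis of the cumulative selection response
#'
#' Propagates parameter uncertainty through the whole selection chain. Each
#' draw samples stream-life (initial, final fraction, between-year trend),
#' spawning delay, and survival advantage from independent uniforms, then
#' re-runs the entry reconstruction and cumulative-normal fit for every year
#' (natural spawn-date means are the fitted `mu + delay`), recomputes the
#' per-year differentials against the fixed hatchery spawn means, and
#' accumulates the response over realized brood years. Heritability enters
#' the chain only as a final multiplier, so a single draw set is shared
#' across the requested `h2` levels (equivalent to repeated runs with common
#' random numbers).
#'
#' @param inputs see [selection_inputs()].
#' @param ranges see [mc_ranges()]; ranges with `lo == hi` are degenerate
#'   (deterministic).
#' @param h2 heritability levels (each fixed within a run).
#' @param n_draws number of Monte Carlo draws.
#' @param seed integer seed; identical seeds give identical draw streams,
#'   and extending `n_draws` leaves the first draws unchanged.
#' @param generation_time years per generation.
#' @return An object of class `selection_mc`: list with `draws` (data frame
#'   of parameter draws, the mean effective differential `S_mean`, and one
#'   `cumulative_h2_*` column per level), `summary` (median, IQR, proportion
#'   of draws advancing timing, per level), `h2`, `n_draws`, `multiplier`.
#' @examples
#' scn <- simulate_scenario(reference_scenario(years = 2000:2009,
#'                                             run_size = 5000))
#' mc <- monte_carlo(selection_inputs(scn), n_draws = 50, seed = 1)
#' mc$summary
#' @export
monte_carlo <- function(inputs, ranges = mc_ranges(),
                        h2 = c(0.3, 0.5, 0.83), n_draws = 10000, seed = 1,
                        generation_time = 4) {
  stopifnot(is.list(ranges),
            all(c("initial", "final_frac", "trend", "delay", "advantage")
                %in% names(ranges)))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L])
      stop("invalid range for '", nm, "': lo > hi")
  }
  stopifnot(all(h2 >= 0 & h2 <= 1.2), n_draws >= 1)
  years <- inputs$years
  ny <- length(years)
  yf <- if (ny == 1L) 0 else (seq_len(ny) - 1L) / (ny - 1L)
  realized <- years + generation_time <= inputs$final_year &
    is.finite(inputs$hatchery_mean)
  if (!any(realized)) stop("no realized brood years in the inputs")
  mult <- sum(realized) / generation_time
  live_v <- lapply(inputs$live, as.numeric)
  live_d <- lapply(inputs$live, days)

  set.seed(as.integer(seed))
  # one row of base uniforms per draw, so extending n_draws leaves the
  # earlier draws unchanged under the same seed
  u <- matrix(stats::runif(5L * n_draws), ncol = 5L, byrow = TRUE)
  scale_u <- function(uu, r) r[1L] + uu * (r[2L] - r[1L])
  draws <- data.frame(
    draw = seq_len(n_draws),
    initial = scale_u(u[, 1L], ranges$initial),
    final_frac = scale_u(u[, 2L], ranges$final_frac),
    trend = scale_u(u[, 3L], ranges$trend),
    delay = scale_u(u[, 4L], ranges$delay),
    advantage = scale_u(u[, 5L], ranges$advantage))

  S_mean <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    sched <- stream_life_schedule(draws$initial[i],
                                  draws$initial[i] * draws$final_frac[i],
                                  draws$trend[i])
    S_sum <- 0
    for (j in which(realized)) {
      L <- .cohort_lifespans(sched, live_d[[j]][1L],
                             live_d[[j]][length(live_d[[j]])], yf[j])
      ent <- .reconstruct_core(live_v[[j]], L)
      tot <- sum(ent)
      cp <- cumsum(ent) / tot
      fit <- .fit_cdf_core(live_d[[j]] + 0.5, cp, thorough = FALSE)
      nat <- fit$mu + draws$delay[i]
      raw <- (1 - inputs$p_hatchery[j]) * (inputs$hatchery_mean[j] - nat)
      S_sum <- S_sum + raw * draws$advantage[i]
    }
    S_mean[i] <- S_sum / sum(realized)
  }
  draws$S_mean <- S_mean
  summ <- lapply(h2, function(h) {
    cum <- h * S_mean * mult
    c(h2 = h, median = stats::median(cum),
      q25 = unname(stats::quantile(cum, 0.25)),
      q75 = unname(stats::quantile(cum, 0.75)),
      prop_negative = mean(cum < 0))
  })
  for (h in h2)
    draws[[sprintf("cumulative_h2_%g", h)]] <- h * S_mean * mult
  structure(list(draws = draws, summary = do.call(rbind, summ), h2 = h2,
                 n_draws = n_draws, multiplier = mult,
                 realized_years = years[realized]),
            class = "selection_mc")
}

#' @export
print.selection_mc <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo selection response: %d draws, %d realized brood years, %.2f generations\n",
    x$n_draws, length(x$realized_years), x$multiplier))
  print(round(x$summary, 3))
  invisible(x)
}

#' @export
plot.selection_mc <- function(x, ...) {
  nh <- length(x$h2)
  op <- graphics::par(mfrow = c(nh, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (h in x$h2) {
    cum <- x$draws[[sprintf("cumulative_h2_%g", h)]]
    graphics::hist(cum, breaks = 40, main = sprintf("h2 = %g", h),
                   xlab = "cumulative change in spawn date (days)", ...)
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}

#' Parameter sensitivity of the Monte Carlo output
#'
#' Linear sensitivity indices: the squared Pearson correlation between each
#' drawn parameter and the per-draw mean effective differential (the h2 and
#' generation multipliers are common to all draws and drop out).
#'
#' @param mc a [monte_carlo()] result.
#' @return named numeric vector of squared correlations.
#' @export
sensitivity <- function(mc) {
  stopifnot(inherits(mc, "selection_mc"))
  pars <- c("initial", "final_frac", "trend", "delay", "advantage")
  out <- vapply(pars, function(p) {
    v <- mc$draws[[p]]
    if (stats::sd(v) == 0) return(0)
    stats::cor(v, mc$draws$S_mean)^2
  }, numeric(1))
  sort(out, decreasing = TRUE)
}
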