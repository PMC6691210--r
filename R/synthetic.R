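#' Scenario configuration for the synthetic-data generator
#'
#' Defines a ground-truth-known study system: a latent normal river-entry
#' distribution per year, stream-life mortality linking entries to live
#' counts, sparse noisy surveys, a hatchery weir that under-samples the
#' earliest and latest fish, egg-take schedules, thermally-marked parental
#' timing groups with heritable spawn timing, and daily flow/temperature
#' series with trends and breaks. Every downstream stage of the package can
#' be exercised against the known truth.
#'
#' Defaults emulate a Cedar-River-like system over the 1991-2015 hatchery
#' era: entry means advancing from day 278 to day 258, entry SD 10 d, run
#' sizes declining from 90,000 to 45,000, stream-life declining within season
#' from 18 to 11 days with a -2 day between-year trend, spawning delay 8 d,
#' surveys every ~7 days with multiplicative lognormal noise (CV 0.15), and
#' hatchery egg-to-fry survival 0.93 vs 0.17 naturally.
#'
#' @param years integer vector of consecutive study years.
#' @param entry_mean true mean entry day-of-year; scalar or one per year.
#'   Must lie in `[180, 365]`.
#' @param entry_sd true SD of entry date (days).
#' @param run_size total river entrants per year; scalar or one per year.
#' @param stream_life a [stream_life_schedule] (the truth).
#' @param spawning_delay days from river entry to completed spawning.
#' @param survey_interval mean gap between surveys (days); actual gaps are
#'   drawn uniformly from `survey_interval` plus or minus 2 (minimum 2).
#' @param survey_cv coefficient of variation of multiplicative lognormal
#'   survey count noise (0 = exact counts).
#' @param weir_open,weir_close day-of-year the broodstock weir operates;
#'   scalar, one per year, or `NULL` for the default rule (open at
#'   `mu - 1.5 sd`, close at `mu + 0.85 sd`, emulating late installation and
#'   high-flow closure).
#' @param hatchery_fraction probability that an entrant passing the operating
#'   weir is trapped for hatchery spawning.
#' @param h2_true true heritability of spawn date in `[0, 1]`.
#' @param egg_to_fry_hatchery,egg_to_fry_natural egg-to-fry survival
#'   proportions (hatchery must be at least natural).
#' @param fecundity eggs per spawned female.
#' @param otolith_sample otolith records (returning adults sampled) per brood
#'   year.
#' @param p_age4 probability a returning adult is age 4 (else age 5).
#' @param env list of environmental-series parameters; see
#'   [generate_environment()] for the recognised names and defaults.
#' @param seed integer seed; identical configurations and seeds reproduce
#'   byte-identical data.
#' @return An object of class `scenario_config` (a validated list with
#'   per-year fields resolved to vectors).
#' @examples
#' sc <- scenario_config(years = 2000:2002, run_size = 2000)
#' sc$entry_mean
#' @export
scenario_config <- function(years = 1991:2015,
                            entry_mean = NULL,
                            entry_sd = 10,
                            run_size = NULL,
                            stream_life = stream_life_schedule(18, 11, trend = -2),
                            spawning_delay = 8,
                            survey_interval = 7,
                            survey_cv = 0.15,
                            weir_open = NULL,
                            weir_close = NULL,
                            hatchery_fraction = 0.25,
                            h2_true = 0.8,
                            egg_to_fry_hatchery = 0.93,
                            egg_to_fry_natural = 0.17,
                            fecundity = 3200,
                            otolith_sample = 350,
                            p_age4 = 0.8,
                            env = list(),
                            seed = 1L) {
  years <- as.integer(years)
  stopifnot(length(years) >= 1L, !anyNA(years))
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("'years' must be consecutive")
  ny <- length(years)
  rep_y <- function(v, what) {
    if (length(v) == 1L) v <- rep(v, ny)
    if (length(v) != ny) stop("'", what, "' must have length 1 or one per year")
    v
  }
  if (is.null(entry_mean))
    entry_mean <- if (ny == 1L) 272 else seq(278, 258, length.out = ny)
  entry_mean <- rep_y(entry_mean, "entry_mean")
  if (any(entry_mean < 180) || any(entry_mean > 365))
    stop("entry means must lie within day-of-year [180, 365]")
  stopifnot(is.numeric(entry_sd), entry_sd > 0)
  if (is.null(run_size))
    run_size <- if (ny == 1L) 60000 else round(seq(90000, 45000, length.out = ny))
  run_size <- rep_y(run_size, "run_size")
  if (any(run_size <= 0)) stop("run size must be positive: config rejected")
  stopifnot(inherits(stream_life, "stream_life_schedule"))
  stopifnot(spawning_delay >= 0, spawning_delay <= 30)
  stopifnot(survey_interval >= 2)
  stopifnot(survey_cv >= 0)
  for (p in c(hatchery_fraction, h2_true, egg_to_fry_hatchery,
              egg_to_fry_natural, p_age4))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  if (egg_to_fry_natural > egg_to_fry_hatchery)
    stop("'egg_to_fry_natural' must not exceed 'egg_to_fry_hatchery'")
  if (is.null(weir_open))
    weir_open <- round(entry_mean - 1.5 * entry_sd)
  if (is.null(weir_close))
    weir_close <- round(entry_mean + 0.85 * entry_sd)
  weir_open <- rep_y(weir_open, "weir_open")
  weir_close <- rep_y(weir_close, "weir_close")
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  env <- utils::modifyList(.default_env_params(), env)
  structure(list(
    years = years, entry_mean = entry_mean, entry_sd = entry_sd,
    run_size = run_size, stream_life = stream_life,
    spawning_delay = spawning_delay, survey_interval = survey_interval,
    survey_cv = survey_cv, weir_open = weir_open, weir_close = weir_close,
    hatchery_fraction = hatchery_fraction, h2_true = h2_true,
    egg_to_fry_hatchery = egg_to_fry_hatchery,
    egg_to_fry_natural = egg_to_fry_natural, fecundity = fecundity,
    otolith_sample = otolith_sample, p_age4 = p_age4,
    env = env, seed = seed), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d year(s) %d-%d, seed %d\n",
              length(x$years), min(x$years), max(x$years), x$seed))
  cat(sprintf("  entry mean day %.1f..%.1f (sd %.3g), run %s..%s fish\n",
              x$entry_mean[1L], x$entry_mean[length(x$entry_mean)],
              x$entry_sd, format(x$run_size[1L], big.mark = ","),
              format(x$run_size[length(x$run_size)], big.mark = ",")))
  print(x$stream_life)
  cat(sprintf("  delay %g d; surveys ~%g d CV %.2g; weir frac %.2g; h2 %.2g\n",
              x$spawning_delay, x$survey_interval, x$survey_cv,
              x$hatchery_fraction, x$h2_true))
  invisible(x)
}

#' Reference scenario for the selection analysis
#'
#' The package's reference synthetic scenario: the study-era defaults of
#' [scenario_config()] with the weir closing at the 60th percentile of each
#' year's entry distribution, so the late 40% of the run is never available
#' for hatchery spawning (the persistent high-flow closure pattern). Used to
#' exercise the full selection-response chain.
#'
#' @param ... overrides passed to [scenario_config()].
#' @export
reference_scenario <- function(...) {
  dots <- list(...)
  base <- do.call(scenario_config, dots)
  if (!("weir_close" %in% names(dots)))
    dots$weir_close <- round(base$entry_mean + stats::qnorm(0.6) * base$entry_sd)
  do.call(scenario_config, dots)
}

# internal: deterministic per-year RNG seed (kept below 2^31)
.year_seed <- function(config, year, stage = 0L) {
  idx <- match(year, config$years)
  if (is.na(idx)) stop("year ", year, " not within the configured range")
  (abs(config$seed) %% 1000003L) * 2000L + idx * 10L + stage
}

.year_frac <- function(config, year) {
  ny <- length(config$years)
  if (ny == 1L) 0 else (match(year, config$years) - 1L) / (ny - 1L)
}

# internal: discretized normal entry probabilities on an integer day grid
# (day d carries mass of [d - 1/2, d + 1/2))
.entry_grid <- function(mu, sd) {
  first <- max(1L, floor(mu - 5 * sd))
  last <- min(365L, ceiling(mu + 5 * sd))
  d <- seq.int(first, last)
  p <- stats::pnorm(d + 0.5, mu, sd) - stats::pnorm(d - 0.5, mu, sd)
  list(days = d, probs = p / sum(p))
}

#' Generate one year's run: true entries, live counts, and surveys
#'
#' Daily entries are a multinomial draw of the year's run size over a
#' discretized normal entry distribution, so entries always sum exactly to
#' the run size. Live counts are the forward cohort sum: entrants of day `d`
#' persist for their cohort stream-life (declining linearly with entry date
#' from `initial` to `final` across the entry window). Surveys sample the
#' live counts every ~`survey_interval` days with multiplicative lognormal
#' noise (mean 1, CV `survey_cv`).
#'
#' @param config a [scenario_config].
#' @param year a year within the configured range.
#' @return list with `entries` and `live` ([daily_series]) and `surveys`
#'   (data frame `year`, `day`, `live_count`), plus `anchor`, the entry
#'   window the stream-life schedule was anchored on.
#' @examples
#' run <- generate_run(scenario_config(years = 2000, run_size = 1000), 2000)
#' sum(run$entries) == 1000
#' @export
generate_run <- function(config, year) {
  stopifnot(inherits(config, "scenario_config"))
  idx <- match(year, config$years)
  if (is.na(idx)) stop("year ", year, " not within the configured range")
  set.seed(.year_seed(config, year, 0L))
  mu <- config$entry_mean[idx]
  grid <- .entry_grid(mu, config$entry_sd)
  n <- config$run_size[idx]
  counts <- as.numeric(stats::rmultinom(1L, n, grid$probs))
  entries <- daily_series(counts, grid$days[1L], year)
  yf <- .year_frac(config, year)
  L <- .cohort_lifespans(config$stream_life, grid$days[1L],
                         grid$days[length(grid$days)], yf)
  # forward cohort sum
  last_live <- grid$days[length(grid$days)] + max(L)
  live <- numeric(last_live - grid$days[1L] + 1L)
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    span <- i:(i + L[i] - 1L)
    live[span] <- live[span] + counts[i]
  }
  live <- daily_series(live, grid$days[1L], year)
  # sparse surveys across the live window
  dl <- days(live)
  sdays <- dl[1L]
  repeat {
    gap <- sample(max(2L, config$survey_interval - 2L):(config$survey_interval + 2L), 1L)
    nxt <- sdays[length(sdays)] + gap
    if (nxt >= dl[length(dl)]) { sdays <- c(sdays, dl[length(dl)]); break }
    sdays <- c(sdays, nxt)
  }
  obs <- as.numeric(live)[sdays - dl[1L] + 1L]
  if (config$survey_cv > 0) {
    sdlog <- sqrt(log(1 + config$survey_cv^2))
    obs <- obs * stats::rlnorm(length(obs), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  surveys <- data.frame(year = year, day = sdays, live_count = obs)
  list(entries = entries, live = live, surveys = surveys,
       anchor = c(grid$days[1L], grid$days[length(grid$days)]))
}

# internal: expected (deterministic) hatchery parental-group means per year,
# used to scale the cohort-environment variance of offspring timing.
# Returns a 3 x n_years matrix of expected early/middle/late egg-take dates.
.expected_parent_group_means <- function(config) {
  vapply(seq_along(config$years), function(i) {
    grid <- .entry_grid(config$entry_mean[i], config$entry_sd)
    keep <- grid$days >= config$weir_open[i] & grid$days <= config$weir_close[i]
    d <- grid$days[keep] + config$spawning_delay
    p <- grid$probs[keep]
    if (!length(d) || sum(p) <= 0) return(rep(NA_real_, 3L))
    p <- p / sum(p)
    cp <- cumsum(p)
    g <- findInterval(cp - 1e-12, c(1 / 3, 2 / 3)) + 1L
    vapply(1:3, function(k) {
      if (!any(g == k)) return(NA_real_)
      sum(d[g == k] * p[g == k]) / sum(p[g == k])
    }, numeric(1))
  }, numeric(3))
}

#' Generate one year's hatchery data: egg take and otolith records
#'
#' Fish entering while the weir operates are trapped with probability
#' `hatchery_fraction` (binomial thinning); trapped females are spawned
#' `spawning_delay` days after capture, producing the egg-take schedule.
#' Egg takes are split into early/middle/late parental timing groups
#' (terciles by cumulative egg count, mirroring thermal otolith marking).
#' Returning offspring carry their parental group and an own spawn date
#' drawn from a stationary-variance infinitesimal model: the offspring group
#' deviation equals `h2_true` times the parental-group deviation plus a
#' shared cohort-environment deviate (variance `(1 - h2^2)` times the
#' parental between-group variance) plus individual noise, so the
#' parent-offspring regression is centred on `h2_true`.
#'
#' @param config a [scenario_config].
#' @param year a year within the configured range.
#' @param entries the year's true entries ([daily_series]) from
#'   [generate_run()].
#' @return list with `egg_take` (data frame `year`, `day`, `females`,
#'   `eggs`), `otoliths` (data frame `brood_year`, `return_year`, `age`,
#'   `parental_group`, `spawn_date`), `parent_groups` (realised egg-weighted
#'   group mean dates), and `p_hatchery` (proportion of the return spawned in
#'   the hatchery).
#' @export
generate_hatchery <- function(config, year, entries) {
  stopifnot(inherits(config, "scenario_config"), inherits(entries, "daily_series"))
  idx <- match(year, config$years)
  if (is.na(idx)) stop("year ", year, " not within the configured range")
  set.seed(.year_seed(config, year, 1L))
  d <- days(entries)
  n_d <- as.numeric(entries)
  open <- config$weir_open[idx]; close <- config$weir_close[idx]
  in_weir <- d >= open & d <= close
  if (!any(in_weir)) {
    warning("empty weir window in ", year, ": zero hatchery take")
    return(list(egg_take = data.frame(year = integer(), day = integer(),
                                      females = integer(), eggs = numeric()),
                otoliths = data.frame(), parent_groups = data.frame(),
                p_hatchery = 0))
  }
  trapped <- integer(length(d))
  trapped[in_weir] <- stats::rbinom(sum(in_weir), size = n_d[in_weir],
                                    prob = config$hatchery_fraction)
  take <- which(trapped > 0)
  females <- stats::rbinom(length(take), trapped[take], 0.5)
  egg_take <- data.frame(year = year,
                         day = d[take] + config$spawning_delay,
                         females = females,
                         eggs = females * config$fecundity)
  egg_take <- egg_take[egg_take$eggs > 0, , drop = FALSE]
  p_hatchery <- sum(trapped) / sum(n_d)
  if (nrow(egg_take) == 0L)
    return(list(egg_take = egg_take, otoliths = data.frame(),
                parent_groups = data.frame(), p_hatchery = p_hatchery))
  # early/middle/late terciles by cumulative egg count
  grp <- .tercile_groups(egg_take$day, egg_take$eggs)
  egg_take$parental_group <- grp
  gm <- tapply(egg_take$day * egg_take$eggs, grp, sum) /
        tapply(egg_take$eggs, grp, sum)
  parent_groups <- data.frame(brood_year = year,
                              parental_group = names(gm),
                              mean_date = as.numeric(gm),
                              eggs = as.numeric(tapply(egg_take$eggs, grp, sum)))
  # offspring spawn dates: stationary-variance infinitesimal model
  em <- .expected_parent_group_means(config)
  G <- mean(em, na.rm = TRUE)                     # grand parental mean date
  sigma_p <- stats::sd(em[is.finite(em)]) * sqrt((sum(is.finite(em)) - 1) /
                                                 sum(is.finite(em)))
  sigma_g <- sqrt(max(0, 1 - config$h2_true^2)) * sigma_p
  n_oto <- config$otolith_sample
  shares <- parent_groups$eggs / sum(parent_groups$eggs)
  n_per <- pmax(1L, round(n_oto * shares))
  oto <- do.call(rbind, lapply(seq_len(nrow(parent_groups)), function(k) {
    nk <- n_per[k]
    dev <- parent_groups$mean_date[k] - G
    e_g <- stats::rnorm(1L, 0, sigma_g)
    dates <- G + config$h2_true * dev + e_g +
      stats::rnorm(nk, 0, config$entry_sd)
    age <- ifelse(stats::runif(nk) < config$p_age4, 4L, 5L)
    data.frame(brood_year = year, return_year = year + age, age = age,
               parental_group = parent_groups$parental_group[k],
               spawn_date = round(dates))
  }))
  list(egg_take = egg_take[, c("year", "day", "females", "eggs",
                               "parental_group")],
       otoliths = oto, parent_groups = parent_groups,
       p_hatchery = p_hatchery)
}

# internal: early/middle/late terciles by cumulative weight along sorted days
.tercile_groups <- function(day, w) {
  o <- order(day)
  cw <- cumsum(w[o]) / sum(w)
  g <- findInterval(cw - 1e-12, c(1 / 3, 2 / 3)) + 1L
  out <- character(length(day))
  out[o] <- c("early", "middle", "late")[g]
  factor(out, levels = c("early", "middle", "late"))
}

.default_env_params <- function() {
  list(temp_mean = 11, temp_amp = 7, temp_peak_day = 220,
       temp_trend = 0.02, temp_sd = 0.3,
       flow_base = 10, flow_amp = 6, flow_min_day = 170,
       flow_ar = 0.7, flow_sd = 0.08,
       freshet_rate_sep = 2, freshet_rate_oct = 4,
       freshet_rate_trend = 0, freshet_break_year = NA,
       freshet_break_delta = 0, freshet_mag = 2)
}

#' Generate one year's daily discharge and temperature series
#'
#' Temperature is a seasonal sinusoid (peaking near `temp_peak_day`) plus a
#' linear warming trend and Gaussian noise. Discharge is a seasonal baseline
#' (minimum near `flow_min_day`, i.e. late summer) with multiplicative AR(1)
#' noise and freshet spikes: Poisson-count rainfall events during
#' September-November whose September frequency can follow a linear trend
#' and/or a step change at `freshet_break_year`, each spike decaying over a
#' few days.
#'
#' @param config a [scenario_config]; parameters are taken from
#'   `config$env` (see [scenario_config()]).
#' @param year a year within the configured range.
#' @return list with `discharge` and `temperature` ([daily_series] over days
#'   1-365).
#' @export
generate_environment <- function(config, year) {
  stopifnot(inherits(config, "scenario_config"))
  idx <- match(year, config$years)
  if (is.na(idx)) stop("year ", year, " not within the configured range")
  set.seed(.year_seed(config, year, 2L))
  p <- config$env
  d <- 1:365
  temp <- p$temp_mean + p$temp_amp * cos(2 * pi * (d - p$temp_peak_day) / 365) +
    p$temp_trend * (idx - 1L)
  if (p$temp_sd > 0) temp <- temp + stats::rnorm(365, 0, p$temp_sd)
  flow <- p$flow_base + p$flow_amp * (-cos(2 * pi * (d - p$flow_min_day) / 365))
  flow <- pmax(flow, 0.5)
  if (p$flow_sd > 0) {
    eps <- numeric(365)
    eps[1L] <- stats::rnorm(1, 0, p$flow_sd)
    innov <- stats::rnorm(364, 0, p$flow_sd * sqrt(1 - p$flow_ar^2))
    for (t in 2:365) eps[t] <- p$flow_ar * eps[t - 1L] + innov[t - 1L]
    flow <- flow * exp(eps)
  }
  # freshet spikes
  rate_sep <- p$freshet_rate_sep + p$freshet_rate_trend * (idx - 1L)
  if (!is.na(p$freshet_break_year) && year >= p$freshet_break_year)
    rate_sep <- rate_sep + p$freshet_break_delta
  rate_sep <- max(0, rate_sep)
  spike_days <- integer(0)
  if (rate_sep > 0) {
    k <- stats::rpois(1L, rate_sep)
    if (k > 0) spike_days <- c(spike_days, sample(244:273, k, replace = TRUE))
  }
  if (p$freshet_rate_oct > 0) {
    k <- stats::rpois(1L, p$freshet_rate_oct)
    if (k > 0) spike_days <- c(spike_days, sample(274:334, k, replace = TRUE))
  }
  for (s in spike_days) {
    mag <- p$freshet_mag * p$flow_base * stats::rlnorm(1L, 0, 0.3)
    span <- s:min(365L, s + 4L)
    flow[span] <- flow[span] + mag * exp(-(span - s) / 1.5)
  }
  list(discharge = daily_series(flow, 1L, year),
       temperature = daily_series(temp, 1L, year))
}

#' Simulate a full multi-year scenario
#'
#' Runs [generate_run()], [generate_hatchery()] and [generate_environment()]
#' for every configured year and assembles the tables every pipeline stage
#' reads, together with the ground truth.
#'
#' @param config a [scenario_config].
#' @return An object of class `run_scenario`: list with `config`, `surveys`,
#'   `egg_take`, `otoliths`, `parent_groups`, `env_daily` (data frames),
#'   `entries`, `live` (lists of [daily_series] keyed by year), `anchors`,
#'   and `ground_truth` (data frame `year`, `true_entry_mean`,
#'   `true_entry_sd`, `true_h2`, `true_differential`, `p_hatchery`,
#'   `run_size`).
#' @examples
#' sc <- scenario_config(years = 2000:2001, run_size = 3000,
#'                       otolith_sample = 50)
#' scn <- simulate_scenario(sc)
#' head(scn$surveys)
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  runs <- lapply(config$years, function(y) generate_run(config, y))
  names(runs) <- config$years
  hatch <- lapply(config$years, function(y)
    generate_hatchery(config, y, runs[[as.character(y)]]$entries))
  names(hatch) <- config$years
  env <- lapply(config$years, function(y) generate_environment(config, y))
  names(env) <- config$years
  surveys <- do.call(rbind, lapply(runs, `[[`, "surveys"))
  egg_take <- do.call(rbind, lapply(hatch, `[[`, "egg_take"))
  otoliths <- do.call(rbind, lapply(hatch, function(h)
    if (is.data.frame(h$otoliths) && nrow(h$otoliths)) h$otoliths))
  parent_groups <- do.call(rbind, lapply(hatch, function(h)
    if (is.data.frame(h$parent_groups) && nrow(h$parent_groups)) h$parent_groups))
  env_daily <- do.call(rbind, lapply(env, function(e)
    data.frame(year = attr(e$discharge, "year"), day = days(e$discharge),
               discharge_cms = as.numeric(e$discharge),
               temp_c = as.numeric(e$temperature))))
  rownames(surveys) <- rownames(egg_take) <- rownames(env_daily) <- NULL
  if (!is.null(otoliths)) rownames(otoliths) <- NULL
  if (!is.null(parent_groups)) rownames(parent_groups) <- NULL
  gt <- do.call(rbind, lapply(seq_along(config$years), function(i) {
    y <- config$years[i]
    h <- hatch[[i]]
    nat_mean <- config$entry_mean[i] + config$spawning_delay
    hm <- if (nrow(h$egg_take)) sum(h$egg_take$day * h$egg_take$eggs) /
      sum(h$egg_take$eggs) else NA_real_
    raw <- if (is.na(hm)) NA_real_ else (1 - h$p_hatchery) * (hm - nat_mean)
    data.frame(year = y, true_entry_mean = config$entry_mean[i],
               true_entry_sd = config$entry_sd, true_h2 = config$h2_true,
               true_differential = raw, p_hatchery = h$p_hatchery,
               run_size = config$run_size[i])
  }))
  structure(list(config = config, surveys = surveys, egg_take = egg_take,
                 otoliths = otoliths, parent_groups = parent_groups,
                 env_daily = env_daily,
                 entries = lapply(runs, `[[`, "entries"),
                 live = lapply(runs, `[[`, "live"),
                 anchors = lapply(runs, `[[`, "anchor"),
                 ground_truth = gt),
            class = "run_scenario")
}

#' @export
print.run_scenario <- function(x, ...) {
  cat(sprintf("<run_scenario> %d year(s), %d surveys, %d egg-take days, %s otolith records\n",
              length(x$config$years), nrow(x$surveys), nrow(x$egg_take),
              if (is.null(x$otoliths)) 0L else nrow(x$otoliths)))
  invisible(x)
}
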