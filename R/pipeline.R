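#' Pipeline configuration
#'
#' Validates and bundles everything [run_pipeline()] needs. Every parameter
#' block is checked against its module invariants before any stage runs, so
#' configuration errors surface immediately and name the offending field.
#'
#' @param scenario a [scenario_config()]; when given, stage inputs are
#'   simulated (with known ground truth written alongside). Alternatively
#'   supply `input_dir` containing `surveys.csv`, `hatchery_eggs.csv`,
#'   `otoliths.csv`, `env_daily.csv` with the package's schemas.
#' @param input_dir directory of input CSVs (ignored when `scenario` is
#'   given).
#' @param output_dir directory for all stage outputs.
#' @param site label used in output tables.
#' @param stream_life,spawning_delay reconstruction point estimates.
#' @param s_hatchery,s_natural egg-to-fry survivals (hatchery must be at
#'   least natural).
#' @param h2_levels heritability levels for the selection stage.
#' @param generation_time years per generation.
#' @param mc_draws Monte Carlo draws.
#' @param percentiles completion fractions for timing summaries.
#' @param seed seed for the Monte Carlo stage.
#' @param figures write PDF figures alongside the tables.
#' @param verbose log stage progress to standard error.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, input_dir = NULL,
                            output_dir = tempfile("runtiming_out_"),
                            site = "synthetic",
                            stream_life = stream_life_schedule(18, 11, trend = -2),
                            spawning_delay = 8,
                            s_hatchery = 0.93, s_natural = 0.17,
                            h2_levels = c(0.3, 0.5, 0.83),
                            generation_time = 4,
                            mc_draws = 2000,
                            percentiles = c(0.10, 0.25, 0.50, 0.75, 0.90),
                            seed = 1L, figures = TRUE, verbose = TRUE) {
  if (is.null(scenario) && is.null(input_dir))
    stop("either 'scenario' or 'input_dir' must be given")
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(input_dir) && is.null(scenario) && !dir.exists(input_dir))
    stop("'input_dir' does not exist: ", input_dir)
  stopifnot(inherits(stream_life, "stream_life_schedule"))
  if (spawning_delay < 0 || spawning_delay > 30)
    stop("'spawning_delay' must lie in [0, 30] days")
  if (s_hatchery <= 0 || s_hatchery > 1)
    stop("'s_hatchery' must lie in (0, 1]")
  if (s_natural < 0 || s_natural > s_hatchery)
    stop("'s_natural' must lie in [0, s_hatchery]: model premise violated")
  stopifnot(all(h2_levels >= 0 & h2_levels <= 1.2), mc_draws >= 1,
            generation_time >= 1,
            all(percentiles > 0 & percentiles < 1))
  structure(list(scenario = scenario, input_dir = input_dir,
                 output_dir = output_dir, site = site,
                 stream_life = stream_life, spawning_delay = spawning_delay,
                 s_hatchery = s_hatchery, s_natural = s_natural,
                 h2_levels = h2_levels, generation_time = generation_time,
                 mc_draws = mc_draws, percentiles = percentiles,
                 seed = as.integer(seed), figures = figures,
                 verbose = verbose),
            class = "pipeline_config")
}

.log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[runtiming] ", sprintf(...))
}

.write_csv <- function(df, cfg, name) {
  path <- file.path(cfg$output_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# add ISO dates next to day-of-year columns for serialized tables
.with_iso_date <- function(df, year_col = "year", day_col = "day") {
  if (all(c(year_col, day_col) %in% names(df)) && nrow(df)) {
    df$date <- as.Date(df[[day_col]] - 1,
                       origin = paste0(df[[year_col]], "-01-01"))
    df$date <- format(df$date, "%Y-%m-%d")
  }
  df
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (when a scenario is configured), entry
#' reconstruction per year, environmental covariates, trend model
#' comparison, realized heritability, selection differentials, and the
#' Monte Carlo sensitivity analysis. Each stage's table is written as CSV to
#' the configured output directory, together with a plain-text summary
#' report and (optionally) PDF figures. Any stage failure raises an error.
#'
#' Output tables: `surveys.csv`, `hatchery_eggs.csv`, `otoliths.csv`,
#' `env_daily.csv`, `ground_truth.csv` (simulated inputs), `entries.csv`,
#' `distributions.csv`, `timing_summary.csv`, `covariates.csv`,
#' `model_table.csv`, `correlations.csv`, `heritability.csv`,
#' `selection_table.csv`, `montecarlo.csv`, and `report.md`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage result and the output paths.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(scenario = scenario_config(years = 2000:2007,
#'                                                   run_size = 4000),
#'                        mc_draws = 50, figures = FALSE, verbose = FALSE)
#' res <- run_pipeline(cfg)
#' names(res$paths)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # stage 1: inputs (simulate or load)
  if (!is.null(cfg$scenario)) {
    .log(cfg, "simulate: %d year(s), seed %d", length(cfg$scenario$years),
         cfg$scenario$seed)
    scn <- simulate_scenario(cfg$scenario)
    surveys <- scn$surveys; egg_take <- scn$egg_take
    otoliths <- scn$otoliths; env_daily <- scn$env_daily
    p_hatchery <- scn$ground_truth[, c("year", "p_hatchery")]
    paths$surveys <- .write_csv(.with_iso_date(surveys), cfg, "surveys.csv")
    paths$hatchery_eggs <- .write_csv(.with_iso_date(egg_take), cfg,
                                      "hatchery_eggs.csv")
    paths$otoliths <- .write_csv(
      .with_iso_date(otoliths, "return_year", "spawn_date"), cfg,
      "otoliths.csv")
    paths$env_daily <- .write_csv(.with_iso_date(env_daily), cfg,
                                  "env_daily.csv")
    paths$ground_truth <- .write_csv(scn$ground_truth, cfg, "ground_truth.csv")
  } else {
    .log(cfg, "load: reading input CSVs from %s", cfg$input_dir)
    read1 <- function(name, required_cols) {
      p <- file.path(cfg$input_dir, name)
      if (!file.exists(p)) stop("missing input file: ", p)
      df <- utils::read.csv(p)
      miss <- setdiff(required_cols, names(df))
      if (length(miss))
        stop("schema violation in ", name, ": missing column(s) ",
             paste(miss, collapse = ", "))
      df
    }
    surveys <- read1("surveys.csv", c("year", "day", "live_count"))
    egg_take <- read1("hatchery_eggs.csv", c("year", "day", "eggs"))
    otoliths <- read1("otoliths.csv",
                      c("brood_year", "age", "parental_group", "spawn_date"))
    env_daily <- read1("env_daily.csv",
                       c("year", "day", "discharge_cms", "temp_c"))
    run_tot <- stats::aggregate(live_count ~ year, surveys, max) # crude scale
    p_hatchery <- NULL
    ph_path <- file.path(cfg$input_dir, "p_hatchery.csv")
    if (file.exists(ph_path)) p_hatchery <- utils::read.csv(ph_path)
  }

  # stage 2: per-year reconstruction
  .log(cfg, "reconstruct: fitting entry distributions")
  years <- sort(unique(surveys$year))
  ny <- length(years)
  fits <- list(); excluded <- integer(0)
  for (i in seq_along(years)) {
    y <- years[i]
    yf <- if (ny == 1L) 0 else (i - 1) / (ny - 1)
    f <- tryCatch(
      run_timing(surveys[surveys$year == y, , drop = FALSE],
                 stream_life = cfg$stream_life,
                 spawning_delay = cfg$spawning_delay, year_frac = yf),
      error = function(e) e)
    if (inherits(f, "error")) {
      .log(cfg, "  year %d excluded: %s", y, conditionMessage(f))
      excluded <- c(excluded, y)
    } else fits[[as.character(y)]] <- f
  }
  if (!length(fits)) stop("no year could be reconstructed")
  used_years <- as.integer(names(fits))
  entries_df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(year = f$year, day = days(f$entries),
               raw_entry = as.numeric(f$entries))
  }))
  dist_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(year = f$year, mu_entry = f$mu_entry, sigma = f$sigma,
               mu_spawn = f$mu_spawn, total_entries = f$total_entries,
               fit_sse = f$sse)))
  tsum <- do.call(rbind, lapply(fits, function(f) {
    tp <- timing_percentiles(.nonneg_series(f$entries),
                             percentiles = cfg$percentiles)
    data.frame(year = f$year, site = cfg$site, t(tp$dates),
               duration = tp$duration)
  }))
  rownames(entries_df) <- rownames(dist_df) <- rownames(tsum) <- NULL
  paths$entries <- .write_csv(.with_iso_date(entries_df), cfg, "entries.csv")
  paths$distributions <- .write_csv(dist_df, cfg, "distributions.csv")
  paths$timing_summary <- .write_csv(tsum, cfg, "timing_summary.csv")

  # stage 3: covariates
  .log(cfg, "covariates: building environmental predictors")
  covars <- build_covariates(env_daily)
  cov_long <- do.call(rbind, lapply(setdiff(names(covars), "year"),
                                    function(v) data.frame(
                                      year = covars$year, covariate = v,
                                      value = covars[[v]])))
  paths$covariates <- .write_csv(cov_long, cfg, "covariates.csv")

  # stage 4: trend model comparison on median spawn timing
  .log(cfg, "trends: fitting the 16-candidate suite")
  tdat <- merge(data.frame(year = dist_df$year, timing = dist_df$mu_spawn),
                covars[, c("year", "E1", "E2")], all.x = TRUE)
  trends <- tryCatch(fit_timing_trends(tdat), error = function(e) e)
  if (inherits(trends, "error")) {
    .log(cfg, "  trends skipped: %s", conditionMessage(trends))
    trends <- NULL
    mt <- data.frame()
  } else {
    mt <- trends$table
    mt$site <- cfg$site
    mt$coefficients <- vapply(mt$id, function(id) {
      b <- trends$fits[[id]]$coef
      paste(sprintf("%s=%.4g", names(b), b), collapse = ";")
    }, character(1))
  }
  paths$model_table <- .write_csv(mt, cfg, "model_table.csv")

  # correlations between timing metrics
  met <- tsum[, c("year", grep("^d\\d+$", names(tsum), value = TRUE),
                  "duration")]
  corr <- tryCatch(timing_correlations(met), error = function(e) NULL)
  corr_df <- if (is.null(corr)) data.frame() else {
    idx <- which(upper.tri(corr$r), arr.ind = TRUE)
    data.frame(metric_a = rownames(corr$r)[idx[, 1L]],
               metric_b = colnames(corr$r)[idx[, 2L]],
               r = corr$r[idx], n = corr$n[idx])
  }
  paths$correlations <- .write_csv(corr_df, cfg, "correlations.csv")

  # stage 5: realized heritability
  .log(cfg, "heritability: parent-offspring regression by age class")
  herit <- NULL
  if (is.data.frame(otoliths) && nrow(otoliths)) {
    rec <- parent_offspring_records(otoliths, egg_take)
    herit <- lapply(c(4, 5), function(a)
      tryCatch(realized_h2(rec, age_class = a), error = function(e) NULL))
    herit <- Filter(Negate(is.null), herit)
  }
  herit_df <- if (length(herit)) do.call(rbind, lapply(herit, function(h)
    data.frame(age_class = h$age_class, h2 = h$h2, ci_lo = h$ci95[1L],
               ci_hi = h$ci95[2L], r2 = h$r2, n = h$n_points)))
    else data.frame()
  paths$heritability <- .write_csv(herit_df, cfg, "heritability.csv")

  # stage 6: selection differentials and expected response
  .log(cfg, "selection: differentials and breeder's-equation response")
  adv <- survival_advantage(cfg$s_hatchery, cfg$s_natural)
  hm <- hatchery_spawn_means(egg_take)
  if (is.null(p_hatchery)) {
    stop("selection stage requires hatchery take proportions ",
         "(p_hatchery) for the population mean weighting")
  }
  sy <- intersect(dist_df$year, hm$year)
  sel <- selection_records(
    years = sy,
    hatchery_mean = hm$hatchery_mean[match(sy, hm$year)],
    natural_mean = dist_df$mu_spawn[match(sy, dist_df$year)],
    p_hatchery = p_hatchery$p_hatchery[match(sy, p_hatchery$year)],
    advantage = adv, h2 = cfg$h2_levels[ceiling(length(cfg$h2_levels) / 2)])
  paths$selection_table <- .write_csv(sel, cfg, "selection_table.csv")
  cum <- lapply(cfg$h2_levels, function(h) cumulative_change(
    breeders_equation(h, sel$S), sel$year, max(years), cfg$generation_time))
  names(cum) <- cfg$h2_levels

  # stage 7: Monte Carlo
  .log(cfg, "montecarlo: %d draws", cfg$mc_draws)
  inputs <- list(years = used_years,
                 live = lapply(fits, `[[`, "live"),
                 hatchery_mean = hm$hatchery_mean[match(used_years, hm$year)],
                 p_hatchery = p_hatchery$p_hatchery[
                   match(used_years, p_hatchery$year)],
                 final_year = max(years))
  inputs$p_hatchery[is.na(inputs$p_hatchery)] <- 0
  mc <- monte_carlo(inputs, h2 = cfg$h2_levels, n_draws = cfg$mc_draws,
                    seed = cfg$seed, generation_time = cfg$generation_time)
  paths$montecarlo <- .write_csv(mc$draws, cfg, "montecarlo.csv")

  # report + figures
  report <- c(
    "# Run-timing analysis report", "",
    sprintf("Site: %s; years %d-%d (%d reconstructed, %d excluded)",
            cfg$site, min(years), max(years), length(fits), length(excluded)),
    sprintf("Entry mean day: %.1f to %.1f; spawning delay %g d",
            dist_df$mu_entry[1L], dist_df$mu_entry[nrow(dist_df)],
            cfg$spawning_delay),
    if (!is.null(trends)) sprintf(
      "Best trend model: %s (Akaike weight %.2f%s)",
      trends$table$id[1L], trends$table$weight[1L],
      if (!is.na(trends$table$break_year[1L]))
        sprintf(", break %d", trends$table$break_year[1L]) else ""),
    if (nrow(herit_df)) sprintf(
      "Realized h2 (age %d): %.2f (95%% CI %.2f-%.2f)",
      herit_df$age_class, herit_df$h2, herit_df$ci_lo, herit_df$ci_hi),
    sprintf("Survival advantage: %.4f", adv),
    sprintf("Mean raw differential: %.2f d; mean S: %.2f d",
            mean(sel$raw, na.rm = TRUE), mean(sel$S, na.rm = TRUE)),
    sprintf("Cumulative change (h2 = %s): %s days over %.2f generations",
            paste(cfg$h2_levels, collapse = "/"),
            paste(sprintf("%.1f", vapply(cum, `[[`, numeric(1), "cumulative")),
                  collapse = "/"),
            cum[[1L]]$multiplier),
    sprintf("Monte Carlo (%d draws): proportion advancing timing %s",
            cfg$mc_draws,
            paste(sprintf("%.2f", mc$summary[, "prop_negative"]),
                  collapse = "/")))
  writeLines(report, file.path(cfg$output_dir, "report.md"))
  paths$report <- file.path(cfg$output_dir, "report.md")

  if (isTRUE(cfg$figures)) {
    grDevices::pdf(file.path(cfg$output_dir, "figures.pdf"), width = 7,
                   height = 9)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    graphics::plot(dist_df$year, dist_df$mu_spawn, type = "b", pch = 16,
                   xlab = "year", ylab = "day of year",
                   main = "Median natural spawn timing")
    sel_ok <- sel[is.finite(sel$raw), ]
    graphics::barplot(sel_ok$raw, names.arg = sel_ok$year, las = 2,
                      ylab = "raw differential (days)",
                      main = "Annual hatchery selection differentials")
    graphics::abline(h = 0)
    plot(mc)
    paths$figures <- file.path(cfg$output_dir, "figures.pdf")
  }

  .log(cfg, "done: outputs in %s", cfg$output_dir)
  invisible(list(fits = fits, distributions = dist_df,
                 timing_summary = tsum, covariates = covars,
                 trends = trends, heritability = herit, selection = sel,
                 cumulative = cum, montecarlo = mc, excluded = excluded,
                 paths = paths))
}
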