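test_that("linear interpolation fills gaps and zero-pads outside the window", {
  s <- data.frame(day = c(1, 5, 9), live_count = c(0, 8, 0))
  out <- interpolate_daily(s)
  expect_equal(out[days(out) == 3], 4, ignore_attr = TRUE)
  # repeated value stays flat between surveys
  s2 <- data.frame(day = c(10, 15, 20), live_count = c(6, 6, 6))
  out2 <- interpolate_daily(s2)
  expect_true(all(as.numeric(out2)[days(out2) >= 10 & days(out2) <= 20] == 6))
  # zero padding one day outside the observed window
  expect_equal(out2[days(out2) == 9], 0, ignore_attr = TRUE)
  expect_equal(out2[days(out2) == 21], 0, ignore_attr = TRUE)
  # too few surveys is an exclusion, not an imputation
  expect_error(interpolate_daily(data.frame(day = c(1, 5), live_count = c(1, 2))),
               "fewer than 3")
  expect_error(interpolate_daily(data.frame(day = c(5, 5, 6),
                                            live_count = c(1, 2, 3))),
               "strictly increasing")
})

test_that("interpolation error on a smooth curve is bounded by local curvature", {
  mu <- 280; sd <- 10; n <- 10000
  d <- 240:320
  curve <- n * (pnorm(d + 0.5, mu, sd) - pnorm(d - 0.5, mu, sd))
  sdays <- seq(241, 319, by = 5)
  surv <- data.frame(day = sdays, live_count = curve[match(sdays, d)])
  out <- interpolate_daily(surv)
  # max second difference of the daily curve bounds the linear-interp error
  curv <- max(abs(diff(curve, differences = 2)))
  bound <- curv * 5^2 / 8 # standard linear interpolation bound, h = 5 days
  common <- intersect(days(out), d)
  err <- max(abs(out[match(common, days(out))] - curve[match(common, d)]))
  expect_lt(err, bound + 1e-9)
})

test_that("deaths/entries recursion reproduces the worked example", {
  live <- daily_series(c(10, 16, 12, 4, 0), 1)
  ent <- reconstruct_entries(live, stream_life_schedule(2))
  expect_equal(as.numeric(ent), c(10, 6, 6, -2, 2))
  # all-zero live counts give all-zero entries
  z <- daily_series(rep(0, 10), 1)
  expect_equal(as.numeric(reconstruct_entries(z, stream_life_schedule(3))),
               rep(0, 10))
})

test_that("recursion agrees exactly with a per-cohort forward oracle", {
  set.seed(42)
  for (rep in 1:200) {
    L <- sample(1:8, 1)
    nd <- sample(5:15, 1)
    entries <- rpois(nd, lambda = sample(1:20, 1))
    live <- cohort_live_oracle(entries, L)
    rec <- reconstruct_entries(daily_series(live, 1), stream_life_schedule(L))
    expect_equal(as.numeric(rec)[seq_along(entries)], entries,
                 ignore_attr = TRUE)
    # conservation: the live series runs to extinction, so total deaths
    # (entries minus the net change in live fish) equal total entries
    lv <- as.numeric(rec) # entries over the full live window
    expect_equal(sum(lv), sum(entries))
  }
})

test_that("round-trip generate -> reconstruct is exact for constant stream-life", {
  for (L in c(10, 15, 20, 25)) {
    sc <- scenario_config(years = 2000, run_size = 10000, survey_cv = 0,
                          stream_life = stream_life_schedule(L),
                          entry_mean = 280, seed = L)
    run <- generate_run(sc, 2000)
    ent <- reconstruct_entries(run$live, sc$stream_life)
    expect_equal(sum(as.numeric(ent)), 10000)
    expect_true(all(as.numeric(ent) >= 0))
    common <- match(days(run$entries), days(ent))
    expect_equal(as.numeric(ent)[common], as.numeric(run$entries))
  }
})

test_that("cumulative-normal fit is self-consistent and handles degeneracy", {
  # exact discretized normal: recover mu within 0.1 d, sigma within 0.2 d
  d <- 230:330
  p <- pnorm(d + 0.5, 280, 10) - pnorm(d - 0.5, 280, 10)
  e <- daily_series(p * 10000, 230)
  f <- fit_entry_cdf(e)
  expect_lt(abs(f$mu - 280), 0.1)
  expect_lt(abs(f$sigma - 10), 0.2)
  # point mass: sigma pinned at its lower bound, mu at the mass
  pm <- daily_series(c(0, 0, 500, 0, 0), 278)
  fpm <- fit_entry_cdf(pm)
  expect_equal(fpm$sigma, 0.01)
  expect_lt(abs(fpm$mu - 280), 0.6)
  # oscillating entries with a negative value still yield a monotone CDF
  osc <- daily_series(c(10, 6, 6, -2, 2), 1)
  fo <- fit_entry_cdf(osc)
  cdf <- pnorm((1:5) + 0.5, fo$mu, fo$sigma)
  expect_true(all(diff(cdf) >= 0))
  expect_error(fit_entry_cdf(daily_series(c(0, 0), 1)), "positive")
})

test_that("fitted entry timing is shift-equivariant in the survey dates", {
  sc <- scenario_config(years = 2000, run_size = 8000, entry_mean = 270,
                        seed = 9)
  run <- generate_run(sc, 2000)
  f1 <- run_timing(run$surveys, stream_life = sc$stream_life)
  s2 <- transform(run$surveys, day = day + 7)
  f2 <- run_timing(s2, stream_life = sc$stream_life)
  expect_equal(f2$mu_entry, f1$mu_entry + 7, tolerance = 1e-6)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-6)
})

test_that("spawning mean is the entry mean offset by the delay", {
  expect_equal(spawning_mean(280, 8), 288)
  expect_equal(spawning_mean(280, 0), 280)
  # the ends of the plausible delay range differ by exactly their spread
  expect_equal(spawning_mean(280, 11) - spawning_mean(280, 5), 6)
  expect_error(spawning_mean(280, 31))
})

test_that("percentile dates use strict exceedance and are monotone", {
  tp <- timing_percentiles(daily_series(c(1, 2, 3, 4), 1))
  expect_equal(unname(tp$dates["d50"]), 3) # cum fractions .1 .3 .6 1.0
  expect_equal(unname(tp$dates["d10"]), 2) # day 1 reaches 0.1 but not strictly
  expect_equal(unname(tp$dates["d90"]), 4)
  expect_equal(tp$duration, 2)
  # point mass: every percentile at the mass, duration zero
  pm <- timing_percentiles(daily_series(c(0, 7, 0), 99))
  expect_true(all(pm$dates == 100))
  expect_equal(pm$duration, 0)
  # symmetric counts put the median on the central day
  sym <- timing_percentiles(daily_series(c(1, 2, 5, 2, 1), 10))
  expect_equal(unname(sym$dates["d50"]), 12)
  expect_error(timing_percentiles(daily_series(rep(0, 5), 1)), "positive")
  # monotone in p for random series
  set.seed(7)
  for (i in 1:25) {
    v <- rpois(sample(5:30, 1), 3) + 0.01
    tp <- timing_percentiles(daily_series(v, sample(1:300, 1)))
    expect_true(all(diff(tp$dates) >= 0))
  }
})

test_that("run_timing methods are coherent", {
  sc <- scenario_config(years = 2000, run_size = 8000, entry_mean = 275,
                        seed = 3)
  run <- generate_run(sc, 2000)
  fit <- run_timing(run$surveys, stream_life = sc$stream_life)
  expect_s3_class(fit, "run_timing")
  expect_named(coef(fit), c("mu_entry", "sigma", "mu_spawn"))
  expect_equal(coef(fit)[["mu_spawn"]], coef(fit)[["mu_entry"]] + 8)
  expect_equal(length(residuals(fit)), length(fit$entries))
  expect_equal(sum(residuals(fit)^2), fit$sse, tolerance = 1e-8)
  pr <- predict(fit, type = "density")
  expect_true(all(pr >= 0))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_equal(length(sim[[1L]]), round(fit$total_entries))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("entry mean", out)))
})
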