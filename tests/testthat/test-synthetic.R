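test_that("generated entries conserve the run size on a clean day grid", {
  sc <- scenario_config(years = 2000:2002, run_size = c(5000, 6000, 7000),
                        seed = 11)
  for (y in sc$years) {
    run <- generate_run(sc, y)
    expect_equal(sum(as.numeric(run$entries)), sc$run_size[match(y, sc$years)])
    expect_equal(days(run$entries), seq(min(days(run$entries)),
                                        max(days(run$entries))))
    expect_true(all(diff(run$surveys$day) > 0))
  }
  expect_error(scenario_config(years = 2000, run_size = 0), "positive")
  expect_error(generate_run(sc, 1990), "not within")
})

test_that("a point-mass entry day yields a rectangular live-count pulse", {
  sc <- scenario_config(years = 2000, run_size = 500, entry_sd = 1e-3,
                        entry_mean = 280,
                        stream_life = stream_life_schedule(5), seed = 2)
  run <- generate_run(sc, 2000)
  lv <- as.numeric(run$live)
  d <- days(run$live)
  expect_true(all(lv[d >= 280 & d <= 284] == 500))
  expect_true(all(lv[d < 280 | d > 284] == 0))
})

test_that("identical seeds reproduce byte-identical scenarios, distinct seeds differ", {
  sc <- scenario_config(years = 2000:2001, run_size = 3000, otolith_sample = 60,
                        seed = 21)
  a <- simulate_scenario(sc)
  b <- simulate_scenario(sc)
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$otoliths, b$otoliths)
  expect_identical(a$env_daily, b$env_daily)
  sc2 <- scenario_config(years = 2000:2001, run_size = 3000,
                         otolith_sample = 60, seed = 22)
  c <- simulate_scenario(sc2)
  expect_false(identical(a$surveys$live_count, c$surveys$live_count))
})

test_that("a full-season weir at full take reproduces population timing", {
  sc <- scenario_config(years = 2000, run_size = 20000, entry_mean = 280,
                        weir_open = 1, weir_close = 365,
                        hatchery_fraction = 1, seed = 5)
  run <- generate_run(sc, 2000)
  h <- generate_hatchery(sc, 2000, run$entries)
  expect_equal(h$p_hatchery, 1)
  hm <- sum(h$egg_take$day * h$egg_take$eggs) / sum(h$egg_take$eggs)
  pop <- series_mean_day(run$entries) + sc$spawning_delay
  expect_lt(abs(hm - pop), 0.5)
  # with everything spawned in the hatchery the raw differential is zero
  d <- selection_differential(hm, pop, p_hatchery = 1, advantage = 0.8)
  expect_equal(d$raw, 0)
})

test_that("a weir closing at the entry median selects for earlier fish", {
  sc <- scenario_config(years = 2000, run_size = 20000, entry_mean = 280,
                        weir_open = 1, weir_close = 280,
                        hatchery_fraction = 0.5, seed = 6)
  run <- generate_run(sc, 2000)
  h <- generate_hatchery(sc, 2000, run$entries)
  hm <- sum(h$egg_take$day * h$egg_take$eggs) / sum(h$egg_take$eggs)
  pop <- series_mean_day(run$entries) + sc$spawning_delay
  expect_lt(hm, pop)
  d <- selection_differential(hm, pop, h$p_hatchery, advantage = 0.8)
  expect_lt(d$raw, 0)
  # empty weir window warns and takes nothing
  sc0 <- scenario_config(years = 2000, run_size = 1000, entry_mean = 280,
                         weir_open = 100, weir_close = 101, seed = 6)
  run0 <- generate_run(sc0, 2000)
  expect_warning(h0 <- generate_hatchery(sc0, 2000, run0$entries),
                 "empty weir")
  expect_equal(h0$p_hatchery, 0)
})

test_that("deterministic environment repeats across years; warming trend accumulates", {
  quiet <- list(temp_sd = 0, temp_trend = 0, flow_sd = 0,
                freshet_rate_sep = 0, freshet_rate_oct = 0)
  sc <- scenario_config(years = 2000:2004, env = quiet, seed = 3)
  inc <- vapply(sc$years, function(y) {
    e <- generate_environment(sc, y)
    unname(flow_metrics(e$discharge, long_term_p75 = Inf)["sep_cum_increase"])
  }, numeric(1))
  expect_true(all(abs(inc - inc[1L]) < 1e-9))
  # 0.05 C/yr over 40 years raises the autumn mean by ~2 C
  sc2 <- scenario_config(years = 1971:2010,
                         env = list(temp_sd = 0, temp_trend = 0.05), seed = 3)
  a1 <- seasonal_stats(generate_environment(sc2, 1971)$temperature)["autumn"]
  a40 <- seasonal_stats(generate_environment(sc2, 2010)$temperature)["autumn"]
  expect_equal(unname(a40 - a1), 0.05 * 39, tolerance = 0.3)
})

test_that("ground truth table matches the configuration", {
  sc <- scenario_config(years = 2000:2002, run_size = 4000,
                        otolith_sample = 50, seed = 8)
  scn <- simulate_scenario(sc)
  expect_equal(scn$ground_truth$year, sc$years)
  expect_equal(scn$ground_truth$true_entry_mean, sc$entry_mean)
  expect_equal(scn$ground_truth$true_h2, rep(sc$h2_true, 3))
  expect_true(all(scn$ground_truth$p_hatchery >= 0 &
                  scn$ground_truth$p_hatchery <= 1))
})
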