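test_that("survival advantage follows its formula and rejects bad premises", {
  expect_equal(survival_advantage(0.5, 0.5), 0)
  expect_equal(survival_advantage(0.5, 0), 1)
  expect_equal(survival_advantage(0.93, 0.17), (0.93 - 0.17) / 0.93)
  expect_equal(round(survival_advantage(0.93, 0.17), 4), 0.8172)
  expect_error(survival_advantage(0.5, 0.6), "premise")
  expect_error(survival_advantage(0, 0))
})

test_that("selection differentials weight the population mean by hatchery share", {
  d0 <- selection_differential(280, 280, 0.3, 0.8)
  expect_equal(d0$raw, 0)
  expect_equal(d0$S, 0)
  d <- selection_differential(270, 280, 0.5, 0.8)
  expect_equal(d$raw, -5)
  expect_equal(d$S, -4)
  # weighting a published-scale raw differential by the printed advantage
  expect_equal(round(effective_differential(-3.9, 0.83), 1), -3.2)
})

test_that("breeder's equation is the plain product", {
  expect_equal(breeders_equation(0, -7), 0)
  expect_equal(breeders_equation(0.5, -3.2), -1.6)
  expect_equal(breeders_equation(1, -2.7), -2.7)
  expect_error(breeders_equation(1.5, 1))
})

test_that("cumulative change counts realized generations", {
  # 21 realized selection years at a 4-year generation time: 5.25 generations
  expect_equal(generation_multiplier(1991:2011, 2015, 4), 5.25)
  expect_equal(generation_multiplier(1991:2015, 2015, 4), 5.25)
  cc <- cumulative_change(rep(-2, 25), 1991:2015, 2015)
  expect_equal(cc$multiplier, 5.25)
  expect_equal(cc$cumulative, -10.5)
  expect_equal(cc$realized_years, 1991:2011)
  expect_equal(cumulative_change(rep(0, 25), 1991:2015, 2015)$cumulative, 0)
  expect_error(cumulative_change(-1, 2015, 2015), "realized")
  # linearity: scaling the responses scales the cumulative change
  dz <- rnorm(25, -2)
  a <- cumulative_change(dz, 1991:2015, 2015)$cumulative
  b <- cumulative_change(3 * dz, 1991:2015, 2015)$cumulative
  expect_equal(b, 3 * a, tolerance = 1e-12)
})

# one small reference scenario shared by the Monte Carlo tests
mc_scenario <- local({
  scn <- simulate_scenario(reference_scenario(years = 2000:2009,
                                              run_size = 8000, seed = 33))
  selection_inputs(scn)
})

test_that("degenerate ranges reproduce the deterministic chain exactly", {
  mc <- monte_carlo(mc_scenario, ranges = mc_ranges(point = TRUE),
                    h2 = 0.5, n_draws = 5, seed = 1)
  expect_equal(length(unique(mc$draws$cumulative_h2_0.5)), 1L)
  # deterministic value recomputed through the user-facing chain
  pe <- mc_point_estimates()
  sched <- stream_life_schedule(pe$initial, pe$initial * pe$final_frac,
                                pe$trend)
  yrs <- mc_scenario$years
  ny <- length(yrs)
  nat <- vapply(seq_along(yrs), function(i) {
    f <- run_timing(live = mc_scenario$live[[i]], stream_life = sched,
                    spawning_delay = pe$delay,
                    year_frac = (i - 1) / (ny - 1))
    f$mu_spawn
  }, numeric(1))
  sel <- selection_records(yrs, mc_scenario$hatchery_mean, nat,
                           mc_scenario$p_hatchery, pe$advantage, h2 = 0.5)
  cc <- cumulative_change(sel$delta_z, yrs, mc_scenario$final_year)
  expect_equal(mc$draws$cumulative_h2_0.5[1L], cc$cumulative,
               tolerance = 1e-6)
})

test_that("the draw stream is reproducible and extendable", {
  a <- monte_carlo(mc_scenario, h2 = 0.5, n_draws = 40, seed = 7)
  b <- monte_carlo(mc_scenario, h2 = 0.5, n_draws = 80, seed = 7)
  expect_identical(a$draws$initial, b$draws$initial[1:40])
  expect_identical(a$draws$S_mean, b$draws$S_mean[1:40])
  c2 <- monte_carlo(mc_scenario, h2 = 0.5, n_draws = 40, seed = 7)
  expect_identical(a$draws, c2$draws)
  expect_error(monte_carlo(mc_scenario, ranges = list(
    initial = c(22, 14), final_frac = c(0.5, 1), trend = c(-4, 0),
    delay = c(5, 11), advantage = c(0.6, 0.95))), "lo > hi")
})

test_that("response magnitude grows with heritability when selection is for earlier", {
  mc <- monte_carlo(mc_scenario, h2 = c(0.3, 0.5, 0.83), n_draws = 60,
                    seed = 9)
  med <- mc$summary[, "median"]
  expect_true(all(diff(med) < 0)) # more negative at higher h2
  # the deterministic point estimate lies inside the draw range per level
  pt <- monte_carlo(mc_scenario, ranges = mc_ranges(point = TRUE),
                    h2 = c(0.3, 0.5, 0.83), n_draws = 1, seed = 1)
  for (h in c("cumulative_h2_0.3", "cumulative_h2_0.5", "cumulative_h2_0.83")) {
    expect_gte(pt$draws[[h]][1L], min(mc$draws[[h]]))
    expect_lte(pt$draws[[h]][1L], max(mc$draws[[h]]))
  }
})

test_that("output is most sensitive to stream-life and delay, least to advantage", {
  mc <- monte_carlo(mc_scenario, h2 = 0.5, n_draws = 400, seed = 13)
  s <- sensitivity(mc)
  expect_gt(s[["delay"]] + s[["initial"]] + s[["final_frac"]] + s[["trend"]],
            s[["advantage"]])
})
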