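test_that("standardization matches the population-SD convention", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  # idempotence and affine invariance
  expect_equal(standardize(z), z)
  expect_equal(standardize(5 * c(1, 2, 3) - 40), z)
  expect_error(standardize(rep(2, 5)), "zero-variance")
  # sample convention differs only in scale
  zs <- standardize(c(1, 2, 3), sd_type = "sample")
  expect_equal(zs, c(-1, 0, 1))
})

test_that("perfect inheritance gives slope one; the slope equals Pearson r", {
  rec <- data.frame(parent_mean_date = c(270, 275, 281, 288, 292, 300),
                    offspring_mean_date = c(270, 275, 281, 288, 292, 300),
                    age_class = 4, n_offspring = 50)
  h <- realized_h2(rec, age_class = 4)
  expect_equal(h$h2, 1, tolerance = 1e-10)
  expect_equal(h$r2, 1, tolerance = 1e-10)
  # unweighted standardized slope == Pearson correlation of the raw means
  set.seed(3)
  rec2 <- data.frame(parent_mean_date = rnorm(24, 280, 6),
                     offspring_mean_date = rnorm(24, 280, 6),
                     age_class = 4, n_offspring = rpois(24, 40))
  h2 <- realized_h2(rec2, age_class = 4, weights = "none")
  expect_equal(h2$h2, cor(rec2$parent_mean_date, rec2$offspring_mean_date),
               tolerance = 1e-10)
  # permuting record order leaves the estimate bit-identical
  h2p <- realized_h2(rec2[sample(24), ], age_class = 4, weights = "none")
  expect_identical(h2$h2, h2p$h2)
  expect_error(realized_h2(rec2[1:2, ], age_class = 4), "fewer than 3")
})

test_that("unrelated offspring rarely produce |h2| above 0.5 at n = 24", {
  set.seed(5)
  hits <- sum(replicate(50, {
    rec <- data.frame(parent_mean_date = rnorm(24, 280, 6),
                      offspring_mean_date = rnorm(24, 280, 6),
                      age_class = 4, n_offspring = 40)
    abs(realized_h2(rec, age_class = 4, weights = "none")$h2) < 0.5
  }))
  expect_gte(hits, 45) # >= 90% of seeds
})

test_that("group records assemble egg-weighted parent means by brood year", {
  egg <- data.frame(year = rep(2000, 4), day = c(270, 272, 280, 290),
                    eggs = c(100, 100, 200, 200))
  oto <- data.frame(brood_year = 2000, return_year = 2004, age = 4,
                    parental_group = c("early", "early", "late"),
                    spawn_date = c(270, 274, 291))
  rec <- parent_offspring_records(oto, egg)
  # terciles by egg count: early = days 270+272(+280 partial boundary)
  early <- rec[rec$parental_group == "early", ]
  expect_equal(early$offspring_mean_date, 272)
  expect_equal(early$n_offspring, 2)
  expect_true(all(rec$age_class == 4))
})

test_that("the CI is centred on the slope and uses n - 2 df", {
  set.seed(8)
  p <- rnorm(20, 280, 5)
  rec <- data.frame(parent_mean_date = p,
                    offspring_mean_date = 0.6 * p + rnorm(20, 112, 2),
                    age_class = 5, n_offspring = 30)
  h <- realized_h2(rec, age_class = 5, weights = "none")
  expect_equal(mean(h$ci95), h$h2, tolerance = 1e-10)
  expect_equal(diff(h$ci95), 2 * qt(0.975, 18) * h$se, tolerance = 1e-10)
  expect_true(h$ci95[1L] <= h$h2 && h$h2 <= h$ci95[2L])
})
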