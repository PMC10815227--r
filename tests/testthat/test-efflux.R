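# Cholesterol-efflux arithmetic, triplicate cleaning, and correlations.

test_that("total and specific efflux arithmetic", {
  expect_equal(total_efflux(250, 750), 25.0)
  expect_equal(total_efflux(0, 500), 0.0)
  expect_equal(total_efflux(500, 500), 50.0)
  expect_error(total_efflux(0, 0), "positive")
  # scale invariance
  set.seed(2)
  for (i in 1:20) {
    m <- runif(1, 10, 1e5); l <- runif(1, 10, 1e5); c0 <- runif(1, 0.1, 50)
    expect_equal(total_efflux(c0 * m, c0 * l), total_efflux(m, l))
  }
  expect_equal(specific_efflux(25.0, 5.0), 20.0)
  expect_equal(specific_efflux(5.0, 5.0), 0.0)
  expect_equal(specific_efflux(4.0, 5.0), -1.0)
})

test_that("the 1.15-SD triplicate rule removes the aberrant replicate only", {
  # hand computation: mean 134, sd ~57.2, |200-134|/sd ~ 1.154 >= 1.15
  expect_identical(as.logical(triplicate_clean(c(100, 102, 200))),
                   c(TRUE, TRUE, FALSE))
  expect_identical(as.logical(triplicate_clean(c(10, 10, 10))), rep(TRUE, 3))
  # max deviation is exactly 1 SD: nothing removed
  expect_identical(as.logical(triplicate_clean(c(10, 11, 12))), rep(TRUE, 3))
  expect_error(triplicate_clean(c(1, 2)), "exactly 3")
})

test_that("cleaning removes at most one value over a grid of triplicates", {
  grid <- expand.grid(a = seq(0, 30, by = 3), b = seq(0, 30, by = 3),
                      c = seq(0, 30, by = 3))
  for (i in seq_len(nrow(grid))) {
    keep <- triplicate_clean(as.numeric(grid[i, ]))
    expect_gte(sum(keep), 2)
  }
})

test_that("plate summary reproduces per-sample efflux from its replicates", {
  sim <- default_sim()
  ef <- summarize_efflux(sim$efflux)
  expect_setequal(ef$sample_id, sim$cohort$sample_id)
  expect_true(all(ef$total_efflux_pct > 0 & ef$total_efflux_pct < 100))
  # consistency: the reported value is the mean of the retained replicates
  one <- sim$efflux[sim$efflux$sample_id == ef$sample_id[1], ]
  tots <- total_efflux(one$cpm_medium, one$cpm_lysate)
  keep <- triplicate_clean(tots)
  expect_equal(ef$total_efflux_pct[1], mean(tots[keep]))
  # pre/post cleaning values remain strongly correlated
  expect_gt(cor(ef$total_efflux_pct_raw, ef$total_efflux_pct), 0.8)
})

test_that("efflux-score correlations recover planted structure", {
  coh <- tibble::tibble(sample_id = sprintf("x%02d", 1:10), score = 1:10)
  ef <- tibble::tibble(sample_id = coh$sample_id,
                       specific_efflux_pct = 20 - coh$score)
  r <- efflux_associations(ef, coh)
  expect_equal(r$r[r$variable == "score"], -1)

  # independent efflux at n = 200: negligible correlation
  cfg0 <- simulation_config(n_samples = 200, efflux_r = 0, rng_seed = 31L,
                            outlier_library = FALSE)
  coh0 <- simulate_cohort(cfg0)
  ef0 <- summarize_efflux(simulate_efflux(coh0, cfg0)$plate)
  r0 <- efflux_associations(ef0, coh0)
  expect_lt(abs(r0$r[r0$variable == "score"]), 0.2)

  expect_error(efflux_associations(ef[1:3, ], coh), "at least 4")
})
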