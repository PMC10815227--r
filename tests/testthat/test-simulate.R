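# Synthetic-data generator: determinism, config validation, structural and
# statistical contracts.

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_mirnas = 0), "n_mirnas")
  expect_error(simulation_config(n_samples = 3), "n_samples")
  expect_error(simulation_config(effect_rho = 0), "effect_rho")
  expect_error(simulation_config(effect_rho = 1.2), "effect_rho")
  expect_error(simulation_config(depth_range = c(-1, 10)), "depth_range")
  expect_error(simulation_config(n_mirnas = 2, n_planted_mirna = 2,
                                 n_planted_isomir_only = 1), "planted")
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(n_mirnas = 8, n_samples = 6, rng_seed = 1L,
                           n_planted_mirna = 1, n_planted_isomir_only = 1)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$efflux, b$efflux)
  expect_identical(a$truth, b$truth)
})

test_that("catalog sequences have the expected lengths and alphabet", {
  cfg <- simulation_config(n_mirnas = 100, rng_seed = 7L)
  cat100 <- simulate_catalog(cfg)
  expect_equal(nrow(cat100), 100)
  lens <- nchar(cat100$mature_seq)
  expect_true(all(lens >= 20 & lens <= 24))
  expect_false(any(grepl("[^ACGU]", cat100$mature_seq)))
  expect_true(all(nchar(cat100$flank5) >= 5 & nchar(cat100$flank3) >= 5))
  expect_false(anyDuplicated(cat100$mirna_id) > 0)
})

test_that("cohort spans the risk cutoff and passes hemolysis by default", {
  cfg <- simulation_config(n_samples = 13, rng_seed = 2L)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh), 13)
  expect_true(all(coh$ct_mir23a - coh$ct_mir451a < 7))
  expect_true(all(coh$score >= 0 & coh$score <= 99))

  coh12 <- simulate_cohort(simulation_config(n_samples = 12, rng_seed = 5L))
  expect_true(any(coh12$score >= 75) && any(coh12$score < 75))

  hemo <- simulate_cohort(simulation_config(n_samples = 10, n_hemolytic = 1,
                                            rng_seed = 4L))
  expect_equal(sum(hemo$ct_mir23a - hemo$ct_mir451a >= 7), 1)
})

test_that("count matrix honours depth range, integrality and truth bookkeeping", {
  sim <- default_sim()
  m <- as.matrix(sim$counts[, -(1:2)])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  tot <- colSums(m)
  keep <- colnames(m) != sim$truth$outlier_library_id
  expect_true(all(tot[keep] >= 0.99 * 1e6 & tot[keep] <= 1.01 * 3e6))
  # every truth identifier exists in the generated tables
  tr <- sim$truth$planted
  expect_true(all(tr$feature_id[tr$level == "isomir"] %in% sim$counts$feature_id))
  expect_true(all(tr$feature_id[tr$level == "mirna"] %in% sim$counts$parent))
  expect_true(all(sim$truth$seed_changing_ids %in% sim$counts$feature_id))
  expect_true(sim$truth$outlier_library_id %in% names(sim$counts))

  empty <- simulate_dataset(simulation_config(
    n_mirnas = 6, n_samples = 6, n_planted_mirna = 0,
    n_planted_isomir_only = 0, outlier_library = FALSE, rng_seed = 9L))
  expect_equal(nrow(empty$truth$planted), 0)
})

test_that("planted features hit their rank-correlation target at large n", {
  cfg <- simulation_config(n_samples = 200, effect_rho = 0.95,
                           outlier_library = FALSE, rng_seed = 11L)
  sim <- simulate_dataset(cfg)
  rpm <- rpm_normalize(sim$counts)
  m <- as.matrix(rpm[, -(1:2)])
  rownames(m) <- rpm$feature_id
  tr <- sim$truth$planted[
    sim$truth$planted$scenario %in% c("lead", "isomir_only"), ]
  for (i in seq_len(nrow(tr))) {
    emp <- spearman_rho(m[tr$feature_id[i], ], sim$cohort$score)
    expect_lt(abs(emp - tr$target_rho[i]), 0.05)
  }
  # null features: centred near zero in distribution
  nulls <- setdiff(rpm$feature_id,
                   sim$truth$planted$feature_id[sim$truth$planted$level == "isomir"])
  nr <- apply(m[nulls, ], 1, spearman_rho, y = sim$cohort$score)
  expect_lt(abs(mean(nr)), 0.05)
  expect_lt(sd(nr), 0.15)
})

test_that("isomiR-only parents aggregate to a flat profile at large n", {
  cfg <- simulation_config(n_samples = 200, outlier_library = FALSE,
                           rng_seed = 12L)
  sim <- simulate_dataset(cfg)
  mir <- rpm_normalize(aggregate_mirna(sim$counts))
  m <- as.matrix(mir[, -1])
  rownames(m) <- mir$feature_id
  io_parents <- unique(sim$truth$planted$parent[
    sim$truth$planted$scenario == "isomir_only"])
  for (p in io_parents) {
    expect_lt(abs(spearman_rho(m[p, ], sim$cohort$score)), 0.3)
  }
})

test_that("the efflux plate has triplicates, a blank, and positive CPM", {
  sim <- default_sim()
  plate <- sim$efflux
  expect_equal(sum(plate$is_blank), 1)
  reps <- table(plate$sample_id[!plate$is_blank])
  expect_true(all(reps == 3))
  expect_true(all(plate$cpm_medium > 0 & plate$cpm_lysate > 0))
  # injected aberrant replicates are removed by the cleaning rule, exactly one
  clean <- summarize_efflux(plate)
  ab <- clean[clean$sample_id %in% sim$truth$aberrant_samples, ]
  expect_true(all(ab$n_replicates_kept == 2))
})
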