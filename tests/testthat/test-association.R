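# Spearman screen, permutation p-values, BH, ROC-AUC, superiority.

test_that("spearman_rho matches known values and handles degenerate input", {
  expect_equal(spearman_rho(1:4, c(2, 4, 6, 8)), 1.0)
  # rank formula: 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 sum 10, n = 4 -> 0
  expect_equal(spearman_rho(1:4, c(3, 1, 4, 2)), 0.0)
  expect_true(is.na(spearman_rho(c(2, 2, 2, 2), 1:4)))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(17)
  for (i in 1:25) {
    x <- rnorm(10)
    y <- rnorm(10)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r)
    expect_equal(spearman_rho(x, y^3 + 2 * y), r)
    expect_equal(spearman_rho(-x, y), -r)
  }
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("permutation p-values are seeded, shared-stream and calibrated at the extreme", {
  set.seed(3)
  coh <- simulate_cohort(simulation_config(n_samples = 12, rng_seed = 6L))
  mono <- matrix(sort(rnorm(12))[rank(coh$score, ties.method = "first")],
                 nrow = 1, dimnames = list("mono", coh$sample_id))
  p <- permutation_pvalues(mono, coh$score, n_perm = 10000L, seed = 2L)
  # P(|rho_perm| = 1) is 2/12! per shuffle; far below 0.001 at 10,000 draws
  expect_lte(p$p_perm, 0.001)

  m <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(letters[1:5], NULL))
  p1 <- permutation_pvalues(m, coh$score, n_perm = 200L, seed = 7L)
  p2 <- permutation_pvalues(m, coh$score, n_perm = 200L, seed = 7L)
  expect_identical(p1, p2)
  expect_error(permutation_pvalues(m, coh$score, n_perm = 50), "n_perm")
  expect_error(permutation_pvalues(m, coh$score[-1]), "length")
})

test_that("stratification is >= 75 and ROC requires both classes", {
  expect_identical(stratify_high_low(c(66, 75, 99, 74)),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(roc_auc_ci(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC-AUC matches pair counting, handles ties, and flips with labels", {
  r <- roc_auc_ci(c(10, 9, 8, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  r2 <- roc_auc_ci(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)   # 3 of 4 concordant pairs
  allt <- roc_auc_ci(rep(5, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(allt$auc, 0.5)
  expect_false(allt$discriminative)
  expect_true(allt$auc_ci_low <= allt$auc && allt$auc <= allt$auc_ci_high)

  set.seed(23)
  for (i in 1:25) {
    v <- sample(0:5, 10, replace = TRUE)
    lab <- c(rep(TRUE, 4), rep(FALSE, 6))
    a <- roc_auc_ci(v, lab)$auc
    expect_equal(a, oracle_auc(v, lab), tolerance = 1e-12)
    expect_equal(a + roc_auc_ci(v, !lab)$auc, 1)
  }
})

test_that("the screen gates candidates at |rho| >= 0.55 including negatives", {
  coh <- simulate_cohort(simulation_config(n_samples = 12, rng_seed = 9L))
  s <- coh$score
  # build features with prescribed correlations: exact monotone, anti-monotone,
  # weak, constant
  ranks <- rank(s, ties.method = "first")
  m <- rbind(
    up = sort(runif(12, 10, 100))[ranks],
    down = sort(runif(12, 10, 100))[13 - ranks],
    flat = rep(50, 12),
    noise = runif(12, 10, 100)
  )
  colnames(m) <- coh$sample_id
  tbl <- counts_tbl(m)
  names(tbl)[1] <- "feature_id"
  scr <- screen_associations(tbl, s, n_perm = 500L, seed = 4L)
  res <- scr$results
  expect_true(res$candidate[res$feature_id == "up"])
  expect_true(res$candidate[res$feature_id == "down"])   # negative rho eligible
  expect_equal(scr$excluded$feature_id, "flat")
  expect_true(all(res$significant <= res$candidate))     # significant => candidate
  expect_true(all(res$discriminative <= res$significant, na.rm = TRUE))

  # exact threshold boundary on a constructed rho
  expect_true(abs(res$rho[res$feature_id == "down"]) >= 0.55)
})

test_that("candidates-only BH family matches the spec's literal ordering", {
  coh <- simulate_cohort(simulation_config(n_samples = 12, rng_seed = 10L))
  set.seed(1)
  m <- matrix(runif(30 * 12, 10, 100), 30, 12,
              dimnames = list(sprintf("f%02d", 1:30), coh$sample_id))
  m[1, ] <- sort(m[1, ])[rank(coh$score, ties.method = "first")]
  tbl <- counts_tbl(m)
  scr_f <- screen_associations(tbl, coh$score, n_perm = 400L, seed = 5L,
                               p_family = "filtered")
  scr_c <- screen_associations(tbl, coh$score, n_perm = 400L, seed = 5L,
                               p_family = "candidates")
  expect_true(all(is.na(scr_c$results$p_adj[!scr_c$results$candidate])))
  cand <- scr_c$results$candidate
  expect_equal(scr_c$results$p_adj[cand],
               oracle_bh(scr_c$results$p_perm[cand]))
  expect_equal(scr_f$results$p_adj, oracle_bh(scr_f$results$p_perm))
})

test_that("superiority comparison implements the four criteria and isomiR-only", {
  mk_screen <- function(df, level) {
    structure(list(results = df, level = level, scores = NULL,
                   params = list(cutoff = 75)), class = "isomir_screen")
  }
  iso <- tibble::tibble(
    feature_id = c("p1.a", "p2.a", "p3.a"),
    rho = c(0.8, 0.6, 0.6), candidate = TRUE,
    p_adj = c(0.01, 0.2, 0.04), significant = c(TRUE, FALSE, TRUE),
    auc = c(0.9, 0.7, 0.8), dynamic_range = c(8, 3, 5)
  )
  mir <- tibble::tibble(
    feature_id = c("p1", "p2", "p3"),
    rho = c(0.6, 0.6, 0.1), candidate = c(TRUE, TRUE, FALSE),
    p_adj = c(0.04, 0.2, 0.9), significant = c(TRUE, FALSE, FALSE),
    auc = c(0.8, 0.7, 0.5), dynamic_range = c(5, 3, NA)
  )
  pm <- tibble::tibble(feature_id = c("p1.a", "p2.a", "p3.a"),
                       parent = c("p1", "p2", "p3"))
  cmp <- compare_isomir_vs_parent(mk_screen(iso, "isomir"),
                                  mk_screen(mir, "mirna"), pm)
  # p1.a beats its parent on all four criteria
  expect_true(cmp$superior[cmp$isomir_id == "p1.a"])
  expect_false(cmp$isomir_only[cmp$isomir_id == "p1.a"])
  # p2.a ties its parent everywhere: no superiority
  expect_false(cmp$superior[cmp$isomir_id == "p2.a"])
  # p3: parent dynamic range undefined -> never counts as smaller either
  expect_false(cmp$larger_dynamic_range[cmp$isomir_id == "p3.a"])
  expect_true(cmp$isomir_only[cmp$isomir_id == "p3.a"])
  expect_true(all(cmp$superior <= cmp$stronger_rho))
})

test_that("null permutation p-values are conservative at alpha = 0.05", {
  # quick sanity companion to the full calibration in the acceptance suite
  coh <- simulate_cohort(simulation_config(n_samples = 12, rng_seed = 14L))
  set.seed(2)
  m <- matrix(rlnorm(150 * 12, 4, 1), 150, 12,
              dimnames = list(sprintf("n%03d", 1:150), coh$sample_id))
  p <- permutation_pvalues(m, coh$score, n_perm = 500L, seed = 8L)$p_perm
  expect_gt(mean(p <= 0.05), 0.01)
  expect_lt(mean(p <= 0.05), 0.12)
})
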