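# Quality gates: hemolysis, detection subsets, inter-library correlation,
# outlier scan.

test_that("hemolysis delta-Ct rule is strict at 7 and shift-invariant", {
  r <- hemolysis_check(c(24.0, 27.0, 20.0), c(18.5, 20.0, 20.0))
  expect_equal(r$delta_ct, c(5.5, 7.0, 0.0))
  expect_identical(r$hemolysis_pass, c(TRUE, FALSE, TRUE))
  # only the difference matters
  shifted <- hemolysis_check(c(24.0, 27.0, 20.0) + 3, c(18.5, 20.0, 20.0) + 3)
  expect_equal(shifted$delta_ct, r$delta_ct)
  expect_error(hemolysis_check(NA_real_, 20), "finite")
  expect_error(hemolysis_check(Inf, 20), "finite")
})

test_that("detection subsets match a brute-force tally and are nested", {
  m <- matrix(c(0, 0, 5, 1), nrow = 1)
  tbl <- counts_tbl(m)
  expect_identical(detection_subsets(tbl, 2), "f01")
  expect_identical(detection_subsets(tbl, 3), character(0))
  expect_error(detection_subsets(tbl, 0), "k must lie")
  expect_error(detection_subsets(tbl, 5), "k must lie")

  set.seed(31)
  big <- counts_tbl(matrix(rpois(50 * 6, 0.8), 50, 6))
  mm <- as.matrix(big[, -1])
  for (k in 1:6) {
    brute <- big$feature_id[vapply(seq_len(50), function(i) {
      sum(mm[i, ] >= 1) >= k
    }, logical(1))]
    expect_identical(detection_subsets(big, k), brute)
  }
  for (k in 1:5) {
    expect_true(all(detection_subsets(big, k + 1) %in% detection_subsets(big, k)))
  }
})

test_that("inter-library correlation is Spearman on RPM with known extremes", {
  a <- c(10, 20, 30, 40, 50)
  tbl <- counts_tbl(matrix(c(a, a * 3, rev(a) * 2), ncol = 3,
                           dimnames = list(NULL, c("s1", "s2", "s3"))))
  rho <- interlibrary_correlation(tbl)
  expect_equal(dim(rho), c(3, 3))
  expect_equal(diag(rho), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(rho["s1", "s2"], 1)    # identical ranks after scaling
  expect_equal(rho["s1", "s3"], -1)   # reversed on strictly distinct values

  set.seed(5)
  rnd <- counts_tbl(matrix(rpois(40 * 5, 20), 40, 5))
  got <- interlibrary_correlation(rnd)
  m <- as.matrix(rnd[, -1])
  m <- t(t(m) / colSums(m)) * 1e6
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(got[i, j], oracle_spearman(m[, i], m[, j]), tolerance = 1e-12)
  }
  zero <- counts_tbl(cbind(s1 = c(1, 2), s2 = c(0, 0)))
  expect_error(interlibrary_correlation(zero), "zero total")
})

test_that("outlier scan flags the degenerate library and only it", {
  sim <- default_sim()
  scan <- library_outlier_scan(sim$counts)
  expect_identical(scan$sample_id[scan$outlier], sim$truth$outlier_library_id)
  expect_true(all(scan$n_in_common5 <= scan$n_in_common3))
  expect_true(all(scan$n_in_common3 <= scan$n_detected))
  expect_true(all(abs(scan$median_intercorrelation) <= 1))

  # rescanning after removal flags nothing further
  rest <- sim$counts[, names(sim$counts) != sim$truth$outlier_library_id]
  expect_false(any(library_outlier_scan(rest)$outlier))

  # an all-healthy cohort yields zero outliers
  clean <- simulate_dataset(simulation_config(outlier_library = FALSE,
                                              rng_seed = 21L))
  expect_false(any(library_outlier_scan(clean$counts)$outlier))
})

test_that("identical libraries are never outliers", {
  m <- matrix(rep(c(5, 0, 9, 2, 7), 6), ncol = 6,
              dimnames = list(NULL, sprintf("s%d", 1:6)))
  expect_false(any(library_outlier_scan(counts_tbl(m))$outlier))
})
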