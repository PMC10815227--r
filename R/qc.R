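# Sample quality gates: hemolysis delta-Ct, detection-rate subsets,
# inter-library correlation and outlier identification.

#' Hemolysis check from qPCR Cts
#'
#' Plasma hemolysis is screened with the miR-23a-3p / miR-451a delta-Ct:
#' delta = Ct(miR-23a-3p) - Ct(miR-451a). A sample passes when delta < 7
#' (strict); miR-451a is the erythrocyte marker, so a small delta means
#' little red-blood-cell contamination.
#'
#' @param samples Data frame with `ct_mir23a` and `ct_mir451a` columns (and
#'   usually `sample_id`), or a numeric vector of miR-23a-3p Cts.
#' @param ct_mir451a miR-451a Cts when `samples` is a numeric vector.
#' @return The input tibble with `delta_ct` and `hemolysis_pass` appended
#'   (built from scratch for vector input).
#' @examples
#' hemolysis_check(24.0, 18.5)
#' @export
hemolysis_check <- function(samples, ct_mir451a = NULL) {
  if (is.numeric(samples)) {
    samples <- tibble(ct_mir23a = samples, ct_mir451a = ct_mir451a)
  }
  if (!all(c("ct_mir23a", "ct_mir451a") %in% names(samples))) {
    abort("`samples` must have ct_mir23a and ct_mir451a columns.")
  }
  cts <- c(samples$ct_mir23a, samples$ct_mir451a)
  if (anyNA(cts) || any(!is.finite(cts)) || any(cts <= 0)) {
    abort("Ct values must be finite and positive.")
  }
  samples %>%
    as_tibble() %>%
    mutate(
      delta_ct = .data$ct_mir23a - .data$ct_mir451a,
      hemolysis_pass = .data$delta_ct < 7
    )
}

#' Features present in at least k libraries
#'
#' A feature is "present" in a library when its raw count is >= 1 there.
#'
#' @param counts Raw count table.
#' @param k Minimum number of libraries (1 <= k <= number of libraries).
#' @return Character vector of feature IDs present in >= k libraries.
#' @export
detection_subsets <- function(counts, k) {
  assert_count_table(counts)
  m <- count_matrix(counts)
  if (!is_scalar_number(k) || k < 1 || k > ncol(m)) {
    abort(sprintf("k must lie in [1, %d].", ncol(m)))
  }
  rownames(m)[rowSums(m >= 1) >= k]
}

#' Pairwise inter-library Spearman correlation
#'
#' Computed on RPM-normalised counts over all features; symmetric with unit
#' diagonal.
#'
#' @param counts Raw count table (>= 2 libraries, no zero-total library).
#' @return Numeric matrix (libraries x libraries) of Spearman rho.
#' @export
interlibrary_correlation <- function(counts) {
  assert_count_table(counts)
  if (length(sample_cols(counts)) < 2) abort("need at least 2 libraries.")
  rpm <- rpm_normalize(counts)
  cor(count_matrix(rpm), method = "spearman")
}

#' Library outlier scan
#'
#' Per library, reports the number of detected features, the number it
#' detects among the features present in at least 3 and at least 5 libraries
#' (subsets computed once over all libraries), and the median Spearman
#' correlation with the other libraries. A library is flagged as an outlier
#' when its >=5-subset detection count falls below the lower Tukey fence
#' (Q1 - 1.5 IQR over libraries) or its median inter-library correlation is
#' below `min_cor` (default 0.6).
#'
#' @param counts Raw count table with >= 4 libraries.
#' @param min_cor Inter-library correlation floor.
#' @return Tibble: `sample_id`, `n_detected`, `n_in_common3`, `n_in_common5`,
#'   `median_intercorrelation`, `outlier`.
#' @export
library_outlier_scan <- function(counts, min_cor = 0.6) {
  assert_count_table(counts)
  m <- count_matrix(counts)
  if (ncol(m) < 4) abort("need at least 4 libraries for the outlier scan.")
  common3 <- detection_subsets(counts, 3L)
  common5 <- detection_subsets(counts, min(5L, ncol(m)))
  det <- m >= 1
  rho <- interlibrary_correlation(counts)
  med_rho <- vapply(seq_len(ncol(m)), function(j) {
    median(rho[-j, j])
  }, numeric(1))
  n_c5 <- colSums(det[common5, , drop = FALSE])
  # Tukey fence with a minimum slack of 2% of the subset size: with
  # near-complete detection the IQR collapses to 0 and a bare fence would
  # flag a library missing a single feature by sampling chance
  iqr <- quantile(n_c5, 0.75) - quantile(n_c5, 0.25)
  fence <- quantile(n_c5, 0.25) - max(1.5 * iqr, 0.02 * length(common5))
  tibble(
    sample_id = colnames(m),
    n_detected = colSums(det),
    n_in_common3 = colSums(det[common3, , drop = FALSE]),
    n_in_common5 = n_c5,
    median_intercorrelation = med_rho,
    outlier = n_c5 < fence | med_rho < min_cor
  )
}
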