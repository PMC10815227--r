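# The correlation screen: Spearman rho, permutation-null p-values on a shared
# shuffle stream, Benjamini-Hochberg adjustment, ROC-AUC with DeLong
# confidence intervals, and the screen driver.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Returns NA when
#' either vector is constant (undefined rank correlation).
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Scalar rho in \[-1, 1\], or NA.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("need at least 3 paired observations.")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up: sort ascending, q(i) = min over j >= i of p(j) * m / j,
#' capped at 1, original order restored.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' High/low risk stratification
#'
#' @param scores Scores on the 0-99 percentile scale.
#' @param cutoff Percentile cutoff; high risk is score >= cutoff.
#' @return Logical vector, TRUE = high risk.
#' @export
stratify_high_low <- function(scores, cutoff = 75) {
  scores >= cutoff
}

# shared permutation stream: n_perm row-permutations of 1..n
permutation_stream <- function(n, n_perm, seed) {
  withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })
}

# core of the permutation screen; m is features x samples (RPM), returns
# list(rho, p_perm). One seeded set of score shufflings is reused across all
# features so the screen is jointly reproducible.
perm_screen_core <- function(m, scores, n_perm, seed, add_one = FALSE) {
  n <- ncol(m)
  rf <- row_standardise(row_mid_ranks(m))
  rs0 <- rank(scores, ties.method = "average")
  rs <- rs0 - mean(rs0)
  nrm <- sqrt(sum(rs^2))
  if (nrm == 0) abort("scores are constant; correlation screen undefined.")
  rs <- rs / nrm
  rho <- as.numeric(rf %*% rs)

  perm_idx <- permutation_stream(n, n_perm, seed)
  perm_rs <- matrix(rs[perm_idx], nrow = n_perm)   # permuted normalised ranks
  rho_perm <- rf %*% t(perm_rs)                    # features x n_perm
  hits <- rowSums(abs(rho_perm) >= abs(rho) - 1e-12)
  p <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  p[is.na(rho)] <- NA_real_
  list(rho = rho, p_perm = p)
}

#' Permutation p-values for score-abundance correlations
#'
#' The score assignment is shuffled `n_perm` times (one seeded shuffle stream
#' shared by every feature) and the p-value is the fraction of shuffles whose
#' absolute Spearman rho is at least the observed absolute rho. The plain
#' count / n_perm estimator can return 0; set `add_one` for the
#' (count + 1) / (n_perm + 1) variant.
#'
#' @param counts RPM count table (or numeric matrix, features x samples).
#' @param scores Numeric scores, one per library.
#' @param n_perm Number of shuffles (>= 100; default 10000).
#' @param seed Integer seed for the shuffle stream.
#' @param add_one Use the add-one estimator (strictly positive p-values).
#' @return Tibble: `feature_id`, `rho`, `p_perm`.
#' @export
permutation_pvalues <- function(counts, scores, n_perm = 10000L, seed = 1L,
                                add_one = FALSE) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  if (ncol(m) != length(scores)) {
    abort("scores length must equal the number of libraries.")
  }
  if (n_perm < 100) abort("n_perm must be >= 100.")
  core <- perm_screen_core(m, scores, n_perm, seed, add_one)
  tibble(feature_id = rownames(m) %||% as.character(seq_len(nrow(m))),
         rho = core$rho, p_perm = core$p_perm)
}

#' ROC-AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney U statistic scaled to \[0, 1\] with ties counted
#' one half, oriented as "higher value predicts the high class" (no
#' automatic flip; AUC below 0.5 is allowed). The 95% CI uses DeLong's
#' placement-variance estimator, truncated to \[0, 1\]. A marker is
#' discriminative when the lower CI bound exceeds 0.5.
#'
#' @param values Numeric marker values.
#' @param labels Logical labels (TRUE = high class); both classes must be
#'   present, at least 2 of each for a CI.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `discriminative`.
#' @examples
#' roc_auc_ci(c(10, 9, 8, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
roc_auc_ci <- function(values, labels, conf = 0.95) {
  if (length(values) != length(labels)) abort("values/labels length mismatch.")
  labels <- as.logical(labels)
  x <- values[labels]   # high class
  y <- values[!labels]  # low class
  if (length(x) == 0 || length(y) == 0) {
    abort("both classes must be present for ROC analysis.")
  }
  n1 <- length(x); n0 <- length(y)
  # placements: psi(x_i, y_j) = 1, 1/2, 0 for x > y, x == y, x < y
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  var_auc <- if (n1 >= 2 && n0 >= 2) var(v10) / n1 + var(v01) / n0 else NA_real_
  zq <- qnorm(1 - (1 - conf) / 2)
  ci_low <- if (is.na(var_auc)) NA_real_ else max(0, auc - zq * sqrt(var_auc))
  ci_high <- if (is.na(var_auc)) NA_real_ else min(1, auc + zq * sqrt(var_auc))
  tibble(auc = auc, auc_ci_low = ci_low, auc_ci_high = ci_high,
         discriminative = !is.na(ci_low) && ci_low > 0.5)
}

#' Correlation screen over a feature table
#'
#' The screening cascade applied to features that already passed the
#' abundance filter: Spearman rho against the score for every feature,
#' candidate gating at `|rho| >= rho_threshold` (negative correlations are
#' eligible), permutation p-values on a shared seeded shuffle stream,
#' Benjamini-Hochberg adjustment, and ROC-AUC discrimination between high and
#' low risk (score >= `cutoff`).
#'
#' `p_family` chooses the Benjamini-Hochberg family: `"candidates"` (default)
#' adjusts over the candidate set only, mirroring the screen-then-correct
#' ordering of the original procedure; `"filtered"` adjusts over every
#' screened feature, which restores selection-free false-discovery control at
#' the cost of power at small n (see the methods vignette). In both cases a
#' feature is `significant` only when it is a candidate and p_adj < alpha,
#' and `discriminative` additionally requires the AUC lower CI bound to
#' exceed 0.5.
#'
#' Features with undefined rho (constant profiles) are excluded and listed in
#' the `excluded` element with a reason; when one risk class is empty the ROC
#' columns are NA and a note is recorded.
#'
#' @param rpm RPM count table of abundance-filtered features.
#' @param scores Numeric score vector, one per library (same order as the
#'   sample columns).
#' @param level Label stored with the results (`"isomir"` or `"mirna"`).
#' @param rho_threshold Candidate cutoff on |rho| (default 0.55).
#' @param n_perm,seed,add_one Permutation settings (see
#'   [permutation_pvalues()]).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param cutoff High/low risk score cutoff for ROC (default 75).
#' @param p_family `"candidates"` (default) or `"filtered"`.
#' @param flip_negative When TRUE, AUC for negative-rho features is computed
#'   on the negated values (recorded in `auc_flipped`).
#' @return An object of class `isomir_screen`: list with `results` tibble
#'   (`feature_id`, `level`, `mean_rpm`, `sd_rpm`, `dynamic_range`, `rho`,
#'   `candidate`, `p_perm`, `p_adj`, `significant`, `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `discriminative`, `auc_flipped`), `excluded`, `notes`,
#'   and the screen parameters. Supports [tidy()], [glance()], [autoplot()].
#' @export
screen_associations <- function(rpm, scores, level = "isomir",
                                rho_threshold = 0.55, n_perm = 10000L,
                                seed = 1L, alpha = 0.05, cutoff = 75,
                                p_family = c("candidates", "filtered"),
                                add_one = FALSE, flip_negative = FALSE) {
  p_family <- match.arg(p_family)
  assert_count_table(rpm)
  m <- count_matrix(rpm)
  if (ncol(m) != length(scores)) {
    abort("scores length must equal the number of libraries.")
  }

  core <- perm_screen_core(m, scores, n_perm, seed, add_one)
  summ <- abundance_summary(rpm)
  res <- tibble(
    feature_id = rownames(m),
    level = level,
    mean_rpm = summ$mean_rpm,
    sd_rpm = summ$sd_rpm,
    dynamic_range = summ$dynamic_range,
    rho = core$rho,
    p_perm = core$p_perm
  )

  excluded <- res %>%
    filter(is.na(.data$rho)) %>%
    select("feature_id") %>%
    mutate(reason = "constant feature or score: Spearman rho undefined")
  res <- res %>% filter(!is.na(.data$rho))

  res$candidate <- abs(res$rho) >= rho_threshold
  res$p_adj <- NA_real_
  fam <- if (p_family == "candidates") which(res$candidate) else seq_len(nrow(res))
  if (length(fam) > 0) res$p_adj[fam] <- bh_adjust(res$p_perm[fam])
  res$significant <- res$candidate & !is.na(res$p_adj) & res$p_adj < alpha

  labels <- stratify_high_low(scores, cutoff)
  notes <- character(0)
  if (length(unique(labels)) < 2) {
    notes <- sprintf(
      "ROC skipped: single risk class at cutoff %s (no library on the other side)",
      cutoff)
    roc <- tibble(auc = NA_real_, auc_ci_low = NA_real_,
                  auc_ci_high = NA_real_, discriminative = NA)[rep(1, nrow(res)), ]
    flipped <- rep(NA, nrow(res))
  } else {
    flipped <- flip_negative & res$rho < 0
    roc <- purrr::map2_dfr(res$feature_id, flipped, function(f, fl) {
      v <- m[f, ]
      roc_auc_ci(if (fl) -v else v, labels)
    })
  }
  res <- bind_cols(res, roc)
  res$auc_flipped <- flipped
  res$discriminative <- res$significant & !is.na(res$discriminative) &
    res$discriminative

  structure(
    list(results = res, excluded = excluded, notes = notes,
         level = level, n_samples = ncol(m), scores = scores,
         params = list(rho_threshold = rho_threshold, n_perm = n_perm,
                       seed = seed, alpha = alpha, cutoff = cutoff,
                       p_family = p_family, add_one = add_one,
                       flip_negative = flip_negative)),
    class = "isomir_screen"
  )
}

#' @export
print.isomir_screen <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "<isomir_screen> level=%s: %d features, %d candidates (|rho|>=%.2f), %d significant, %d discriminative\n",
    x$level, nrow(r), sum(r$candidate), x$params$rho_threshold,
    sum(r$significant), sum(r$discriminative, na.rm = TRUE)))
  invisible(x)
}
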