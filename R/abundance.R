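# RPM normalisation, isomiR->miRNA aggregation, the dual abundance filter and
# dynamic range.

#' Reads-per-million normalisation
#'
#' Each library's counts are divided by that library's total isomiR-level
#' read count and scaled to one million. The denominator is the column sum of
#' the full table, so it must be computed before any feature filtering.
#'
#' @param counts Raw count table (tibble: `feature_id`, optional `parent`,
#'   one integer column per library).
#' @return Same shape, RPM values; every retained-library column sums to 1e6.
#' @examples
#' rpm_normalize(tibble::tibble(feature_id = c("a", "b"), s1 = c(1L, 3L)))
#' @export
rpm_normalize <- function(counts) {
  assert_count_table(counts, raw = TRUE)
  m <- count_matrix(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(sprintf("library with zero total count: %s",
                  paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  rpm <- t(t(m) / tot) * 1e6
  out <- counts
  out[, colnames(m)] <- as_tibble(rpm)
  out
}

#' Aggregate isomiR counts to total-miRNA counts
#'
#' The total count of a miRNA in a library is the sum of all its isomiRs'
#' counts there (canonical sequence included); per-library totals are
#' conserved exactly.
#'
#' @param counts IsomiR-level raw count table with a `parent` column.
#' @return miRNA-level count table (`feature_id` = parent miRNA ID).
#' @export
aggregate_mirna <- function(counts) {
  assert_count_table(counts)
  if (!"parent" %in% names(counts)) {
    abort("`counts` must carry a `parent` column to aggregate.")
  }
  sc <- sample_cols(counts)
  counts %>%
    group_by(feature_id = .data$parent) %>%
    summarise(across(all_of(sc), sum), .groups = "drop") %>%
    arrange(match(.data$feature_id, unique(counts$parent)))
}

#' Per-feature abundance summary and filter
#'
#' Summarises each feature's RPM profile and applies the dual abundance
#' filter: mean RPM strictly above `min_mean` and maximal RPM strictly above
#' `min_max` across libraries. The dynamic range is the ratio of the highest
#' to the lowest RPM, undefined (NA) when the minimum is zero. The same rule
#' applies unchanged at isomiR and miRNA level.
#'
#' @param rpm RPM-normalised count table.
#' @param min_mean,min_max Filter thresholds (RPM); defaults 5 and 50.
#' @return Tibble: `feature_id`, `mean_rpm`, `sd_rpm`, `max_rpm`, `min_rpm`,
#'   `dynamic_range`, `passed_filter`.
#' @export
abundance_summary <- function(rpm, min_mean = 5, min_max = 50) {
  assert_count_table(rpm)
  m <- count_matrix(rpm)
  tibble(
    feature_id = rownames(m),
    mean_rpm = unname(rowMeans(m)),
    sd_rpm = unname(apply(m, 1, sd)),
    max_rpm = unname(apply(m, 1, max)),
    min_rpm = unname(apply(m, 1, min))
  ) %>%
    mutate(
      dynamic_range = dynamic_range(.data$max_rpm, .data$min_rpm),
      passed_filter = .data$mean_rpm > min_mean & .data$max_rpm > min_max
    )
}

#' Dynamic range of abundance
#'
#' Ratio between the highest and lowest value of a per-feature RPM profile;
#' undefined (NA) when the minimum is zero.
#'
#' @param max_rpm,min_rpm Numeric vectors (or a single profile via `values`).
#' @param values Optional numeric vector; when given, max/min are taken from
#'   it and the other arguments are ignored.
#' @return Numeric vector of ratios (NA where the minimum is 0).
#' @examples
#' dynamic_range(values = c(10, 40))
#' @export
dynamic_range <- function(max_rpm = NULL, min_rpm = NULL, values = NULL) {
  if (!is.null(values)) {
    max_rpm <- max(values)
    min_rpm <- min(values)
  }
  ifelse(min_rpm > 0, max_rpm / min_rpm, NA_real_)
}
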