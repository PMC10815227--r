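# Shared helpers for the tibble-first count-table layout.
#
# A count table is a tibble with a `feature_id` column, an optional `parent`
# column (isomiR tables only), and one numeric column per sample/library.

ID_COLS <- c("feature_id", "parent")

#' Sample columns of a count table
#'
#' @param counts A count table (tibble with `feature_id`, optional `parent`,
#'   then one numeric column per library).
#' @return Character vector of library column names, in table order.
#' @export
sample_cols <- function(counts) {
  setdiff(names(counts), ID_COLS)
}

# counts tibble -> numeric matrix (features x samples), rownames = feature_id
count_matrix <- function(counts) {
  sc <- sample_cols(counts)
  m <- as.matrix(counts[, sc, drop = FALSE])
  rownames(m) <- counts$feature_id
  m
}

assert_count_table <- function(counts, raw = FALSE) {
  if (!is.data.frame(counts) || !"feature_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a `feature_id` column.")
  }
  sc <- sample_cols(counts)
  if (length(sc) == 0) abort("`counts` has no sample columns.")
  m <- count_matrix(counts)
  if (!is.numeric(m)) abort("sample columns must be numeric.")
  if (anyNA(m)) abort("counts contain missing values.")
  if (any(m < 0)) abort("counts contain negative values.")
  if (raw && any(m != round(m))) abort("raw counts must be integers.")
  invisible(counts)
}

# mid-ranks row-wise; m is features x samples
row_mid_ranks <- function(m) {
  t(apply(m, 1L, rank, ties.method = "average"))
}

# center rows and scale to unit norm; constant rows -> NA rows
row_standardise <- function(m) {
  ctr <- m - rowMeans(m)
  nrm <- sqrt(rowSums(ctr^2))
  nrm[nrm == 0] <- NA_real_
  ctr / nrm
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# derive a child seed from a base seed, kept within 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
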