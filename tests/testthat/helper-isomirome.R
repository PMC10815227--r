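# Shared fixtures and independent brute-force oracles.

# small count table builder: features x samples matrix -> tidy count table
counts_tbl <- function(m, parents = NULL) {
  fid <- rownames(m) %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  out <- tibble::tibble(feature_id = fid)
  if (!is.null(parents)) out$parent <- parents
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Spearman: Pearson on mid-ranks via the definition
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force BH step-up from the definition: q(i) = min_{j>=i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    q[i] <- min(pmin(sorted[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force AUC: all-pairs concordance count with ties = 1/2
oracle_auc <- function(values, labels) {
  x <- values[labels]
  y <- values[!labels]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# default synthetic dataset shared by round-trip tests (computed once)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(simulation_config())
    cache
  }
})
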