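# Readers and writers for the on-disk formats: canonical catalog FASTA (with
# an optional precursor-context companion), the miRGE-style isomiR count TSV,
# the sample metadata TSV, the efflux plate TSV and the simulation-truth JSON
# sidecar.

need_biostrings <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required for FASTA input/output.")
  }
}

#' Read a canonical miRNA catalog from FASTA
#'
#' The mature FASTA holds one record per miRNA (record ID = miRNA ID,
#' sequence = mature sequence). The optional precursor companion FASTA is
#' keyed by the same IDs and carries the mature span in its description line
#' as `mature_start=<int> mature_end=<int>` (1-based, inclusive); the
#' sequence on either side of that span becomes the 5'/3' flank used for
#' templated-extension calls. T is transliterated to U on read.
#'
#' @param mature_fasta Path to the mature-sequence FASTA.
#' @param precursor_fasta Optional path to the precursor-context FASTA.
#' @return Tibble: `mirna_id`, `mature_seq`, `flank5`, `flank3` (empty
#'   strings when no precursor context is available).
#' @export
read_mirna_catalog <- function(mature_fasta, precursor_fasta = NULL) {
  need_biostrings()
  mat <- Biostrings::readBStringSet(mature_fasta)
  ids <- sub("\\s.*$", "", names(mat))
  out <- tibble(
    mirna_id = ids,
    mature_seq = unname(as_rna(as.character(mat))),
    flank5 = "",
    flank3 = ""
  )
  if (anyDuplicated(out$mirna_id)) abort("duplicate miRNA IDs in catalog FASTA.")
  check_rna(out$mature_seq, "mature sequence")

  if (!is.null(precursor_fasta)) {
    pre <- Biostrings::readBStringSet(precursor_fasta)
    pids <- sub("\\s.*$", "", names(pre))
    starts <- as.integer(stringr::str_match(names(pre), "mature_start=(\\d+)")[, 2])
    ends <- as.integer(stringr::str_match(names(pre), "mature_end=(\\d+)")[, 2])
    if (anyNA(starts) || anyNA(ends)) {
      abort("precursor FASTA descriptions must carry mature_start=/mature_end=.")
    }
    seqs <- as_rna(as.character(pre))
    idx <- match(out$mirna_id, pids)
    hit <- !is.na(idx)
    out$flank5[hit] <- substr(seqs[idx[hit]], 1, starts[idx[hit]] - 1)
    out$flank3[hit] <- substr(seqs[idx[hit]], ends[idx[hit]] + 1,
                              nchar(seqs[idx[hit]]))
    span <- substr(seqs[idx[hit]], starts[idx[hit]], ends[idx[hit]])
    if (any(span != out$mature_seq[hit])) {
      abort("precursor mature span disagrees with the mature FASTA sequence.")
    }
  }
  out
}

#' Write a catalog to a mature FASTA plus precursor companion
#'
#' @param catalog Tibble as returned by [simulate_catalog()] /
#'   [read_mirna_catalog()].
#' @param mature_fasta,precursor_fasta Output paths.
#' @return Invisibly, the two paths.
#' @export
write_mirna_catalog <- function(catalog, mature_fasta, precursor_fasta = NULL) {
  need_biostrings()
  mat <- Biostrings::BStringSet(setNames(catalog$mature_seq, catalog$mirna_id))
  Biostrings::writeXStringSet(mat, mature_fasta)
  if (!is.null(precursor_fasta)) {
    pre_seq <- paste0(catalog$flank5, catalog$mature_seq, catalog$flank3)
    starts <- nchar(catalog$flank5) + 1L
    ends <- nchar(catalog$flank5) + nchar(catalog$mature_seq)
    nm <- sprintf("%s mature_start=%d mature_end=%d",
                  catalog$mirna_id, starts, ends)
    pre <- Biostrings::BStringSet(setNames(pre_seq, nm))
    Biostrings::writeXStringSet(pre, precursor_fasta)
  }
  invisible(c(mature_fasta, precursor_fasta))
}

#' Parse a miRGE-style isomiR count table
#'
#' Expects a TSV whose header is `sequence`, `parent`, then one column per
#' library (an optional leading `isomir_id` column is honoured; otherwise
#' stable IDs `<parent>.iso<N>` are assigned). Every accepted row is
#' classified against its canonical parent with [classify_isomir()]. Rows
#' whose parent is absent from the catalog, or whose sequence admits no
#' ungapped placement, are collected into a rejects table with the reason and
#' line number — not silently dropped.
#'
#' @param path TSV path.
#' @param catalog Canonical catalog tibble.
#' @param ... Passed to [classify_isomir()] (offset bounds).
#' @return List: `records` (tibble with IDs, sequences, parents and the
#'   annotation columns), `counts` (count table: `feature_id`, `parent`, one
#'   integer column per library), `rejects` (tibble: `line`, `sequence`,
#'   `parent`, `reason`).
#' @export
parse_isomir_table <- function(path, catalog, ...) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed isomiR table at line %d: %s",
                  probs$row[1] + 1L, probs$expected[1]))
  }
  has_id <- "isomir_id" %in% names(raw)
  need <- c("sequence", "parent")
  if (!all(need %in% names(raw))) {
    abort("isomiR table must have `sequence` and `parent` columns.")
  }
  sc <- setdiff(names(raw), c("isomir_id", need))
  if (length(sc) == 0) abort("isomiR table has no sample columns.")
  cm <- as.matrix(raw[, sc])
  if (!is.numeric(cm) || anyNA(cm)) abort("counts must be numeric and complete.")
  if (any(cm < 0)) abort("negative count in isomiR table.")
  if (any(cm != round(cm))) abort("non-integer count in isomiR table.")

  raw$sequence <- as_rna(raw$sequence)
  if (!has_id) {
    raw <- raw %>%
      group_by(.data$parent) %>%
      mutate(isomir_id = sprintf("%s.iso%d", .data$parent, row_number())) %>%
      ungroup()
  }

  known <- raw$parent %in% catalog$mirna_id
  rejects <- tibble(
    line = which(!known) + 1L,
    sequence = raw$sequence[!known],
    parent = raw$parent[!known],
    reason = "parent absent from catalog"
  )
  acc <- raw[known, , drop = FALSE]

  ann <- vector("list", nrow(acc))
  bad <- logical(nrow(acc))
  reason <- character(nrow(acc))
  cidx <- match(acc$parent, catalog$mirna_id)
  for (i in seq_len(nrow(acc))) {
    res <- tryCatch(
      classify_isomir(acc$sequence[i], catalog$mature_seq[cidx[i]],
                      catalog$flank5[cidx[i]], catalog$flank3[cidx[i]], ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      bad[i] <- TRUE
      reason[i] <- conditionMessage(res)
    } else {
      ann[[i]] <- res
    }
  }
  if (any(bad)) {
    rejects <- bind_rows(rejects, tibble(
      line = which(known)[bad] + 1L,
      sequence = acc$sequence[bad], parent = acc$parent[bad],
      reason = reason[bad]
    ))
    acc <- acc[!bad, , drop = FALSE]
    ann <- ann[!bad]
  }

  records <- bind_cols(
    acc %>% select("isomir_id", "sequence", "parent"),
    bind_rows(ann)
  )
  counts <- bind_cols(
    tibble(feature_id = acc$isomir_id, parent = acc$parent),
    acc[, sc]
  )
  counts[, sc] <- lapply(counts[, sc], as.integer)
  list(records = records, counts = counts,
       rejects = rejects %>% arrange(.data$line))
}

#' Write an isomiR count table to TSV
#'
#' @param counts Count table with `feature_id` and `parent`.
#' @param repertoire Tibble with `isomir_id` and `sequence` (to emit the
#'   sequence column).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_isomir_table <- function(counts, repertoire, path) {
  seqs <- repertoire$sequence[match(counts$feature_id, repertoire$isomir_id)]
  out <- bind_cols(
    tibble(isomir_id = counts$feature_id, sequence = seqs,
           parent = counts$parent),
    counts[, sample_cols(counts)]
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read the sample metadata TSV
#'
#' Columns: `sample_id`, `score`, `ct_mir23a`, `ct_mir451a` (extra columns
#' such as spike-in recovery are carried through untouched).
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_sample_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "score", "ct_mir23a", "ct_mir451a")
  if (!all(need %in% names(x))) {
    abort(sprintf("sample table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  x
}

#' Read an efflux plate TSV
#'
#' Columns: `sample_id`, `replicate_index`, `cpm_medium`, `cpm_lysate`,
#' `is_blank`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_efflux_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "replicate_index", "cpm_medium", "cpm_lysate", "is_blank")
  if (!all(need %in% names(x))) {
    abort(sprintf("efflux table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  x$is_blank <- as.logical(x$is_blank)
  x
}

#' Write a complete synthetic dataset to disk
#'
#' Materialises a [simulate_dataset()] result in the formats the pipeline
#' reads: catalog FASTA + precursor companion, isomiR count TSV, sample TSV,
#' efflux TSV, and the ground-truth JSON sidecar.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'.", dir))
  paths <- list(
    catalog = file.path(dir, "catalog.fasta"),
    precursors = file.path(dir, "precursors.fasta"),
    isomirs = file.path(dir, "isomir_counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    efflux = file.path(dir, "efflux.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_mirna_catalog(sim$catalog, paths$catalog, paths$precursors)
  write_isomir_table(sim$counts, sim$repertoire, paths$isomirs)
  readr::write_tsv(sim$cohort, paths$samples)
  readr::write_tsv(sim$efflux, paths$efflux)
  truth <- sim$truth
  jsonlite::write_json(
    list(planted = truth$planted,
         outlier_library_id = truth$outlier_library_id,
         seed_changing_ids = truth$seed_changing_ids,
         aberrant_samples = truth$aberrant_samples),
    paths$truth, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(paths)
}

#' Simulate and write a fixture dataset in one call
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return Invisibly, the named list of file paths (see [write_fixtures()]).
#' @export
make_fixtures <- function(config = simulation_config(), dir) {
  sim <- simulate_dataset(config)
  write_fixtures(sim, dir)
}
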