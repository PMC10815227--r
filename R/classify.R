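# isomiR classification against a canonical mature miRNA.
#
# An isomiR is any unique sequenced small-RNA read assigned to a miRNA; it may
# be the canonical (database) mature sequence itself or a variant differing in
# 5'/3' length and/or in nucleotide composition. Classification aligns the
# isomiR, without gaps, to the extended canonical axis
# (5' precursor flank + mature + 3' precursor flank) and annotates the variant.

VARIANT_CLASSES <- c("canonical", "iso_5p", "iso_3p", "polymorphic", "mixed")

#' Convert a nucleotide string to the RNA alphabet
#'
#' Upper-cases and transliterates T to U, so DNA-alphabet input tables can be
#' consumed directly.
#'
#' @param x Character vector of sequences.
#' @return Character vector over {A, C, G, U}.
#' @export
as_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,U}: %s",
                  what, paste(head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

#' Seed sequence of a mature miRNA or isomiR
#'
#' The seed is the 6-mer at positions 2-7 (1-based from the 5' end), the
#' primary determinant of mRNA target recognition. Applied to an isomiR's own
#' sequence, so any 5'-end shift changes the seed.
#'
#' @param sequence Character vector of RNA sequences (length >= 7 each).
#' @return Character vector of 6-mers.
#' @examples
#' seed_of("UACCACAGGGUAGAACCACGG")
#' @export
seed_of <- function(sequence) {
  sequence <- as_rna(sequence)
  if (any(nchar(sequence) < 7)) {
    abort("sequences must be at least 7 nt long to extract a seed.")
  }
  substr(sequence, 2L, 7L)
}

#' Classify one isomiR sequence against its canonical miRNA
#'
#' Finds the ungapped placement of the isomiR on the extended canonical axis
#' (5' flank + mature + 3' flank, when flanks are available) that minimises
#' first the number of internal substitutions and then the total end-offset
#' magnitude. Ties are broken towards the canonical register: smaller absolute
#' 5' offset, then smaller absolute 3' offset, then fewer substitutions inside
#' the seed window. Offsets follow the convention: positive 5' offset = the
#' isomiR starts downstream of the canonical start (trimmed), negative =
#' extended upstream; positive 3' offset = extended past the canonical end,
#' negative = trimmed.
#'
#' The variant class is `canonical` (no change), `iso_5p`/`iso_3p` (pure 5'/3'
#' length change), `polymorphic` (same ends, internal substitution(s)) or
#' `mixed`. `seed_changing` is true when the 5' offset is non-zero or any
#' substitution falls at isomiR positions 2-7. `templated` reports whether
#' extended bases match the precursor flank (`unknown` when the flank needed
#' for the call is absent).
#'
#' @param sequence IsomiR RNA sequence (single string).
#' @param mature_seq Canonical mature sequence.
#' @param flank5,flank3 Precursor context on each side of the mature sequence
#'   (may be empty strings when unknown).
#' @param offset_5p,offset_3p Integer length-2 search bounds for the 5' and 3'
#'   offsets.
#' @return One-row tibble: `five_prime_offset`, `three_prime_offset`,
#'   `n_substitutions`, `substitutions` (list-column of tibbles with
#'   `position`, `canonical`, `observed`), `variant_class`, `templated`,
#'   `seed_changing`.
#' @examples
#' classify_isomir("ACGUACGUACGUACGUACGU", "ACGUACGUACGUACGUACGU")
#' @export
classify_isomir <- function(sequence, mature_seq, flank5 = "", flank3 = "",
                            offset_5p = c(-2L, 4L), offset_3p = c(-4L, 4L)) {
  sequence <- as_rna(sequence)
  mature_seq <- as_rna(mature_seq)
  flank5 <- as_rna(flank5 %||% "")
  flank3 <- as_rna(flank3 %||% "")
  check_rna(c(sequence, mature_seq), "sequence")
  if (nzchar(flank5)) check_rna(flank5, "flank5")
  if (nzchar(flank3)) check_rna(flank3, "flank3")

  iso <- strsplit(sequence, "")[[1]]
  mat <- strsplit(mature_seq, "")[[1]]
  f5 <- if (nzchar(flank5)) strsplit(flank5, "")[[1]] else character(0)
  f3 <- if (nzchar(flank3)) strsplit(flank3, "")[[1]] else character(0)
  axis <- c(f5, mat, f3)
  s0 <- length(f5) + 1L                  # axis index of canonical start
  e0 <- length(f5) + length(mat)         # axis index of canonical end
  L <- length(iso)

  best <- NULL
  for (o5 in seq.int(offset_5p[1], offset_5p[2])) {
    o3 <- (o5 + L) - length(mat)
    if (o3 < offset_3p[1] || o3 > offset_3p[2]) next
    # axis positions covered by the isomiR under this placement
    ax <- s0 + o5 - 1L + seq_len(L)
    on_axis <- ax >= 1L & ax <= length(axis)
    in_mature <- on_axis & ax >= s0 & ax <= e0
    ext <- !(ax >= s0 & ax <= e0)        # extension positions (beyond mature)
    mism_mat <- in_mature & iso != axis[pmax(pmin(ax, length(axis)), 1L)]
    n_sub <- sum(mism_mat)
    ext_covered <- ext & on_axis
    ext_uncovered <- ext & !on_axis
    ext_mismatch <- ext_covered & iso != axis[pmax(pmin(ax, length(axis)), 1L)]
    seed_sub <- sum(mism_mat & seq_len(L) >= 2L & seq_len(L) <= 7L)
    cand <- list(o5 = o5, o3 = o3, n_sub = n_sub,
                 sub_pos = which(mism_mat), ax = ax,
                 any_ext = any(ext),
                 ext_3p_mismatch = any(ext_mismatch & seq_len(L) > (e0 - s0 + 1L - o5)),
                 ext_any_mismatch = any(ext_mismatch),
                 ext_unknown = any(ext_uncovered),
                 seed_sub = seed_sub)
    key <- c(n_sub, abs(o5) + abs(o3), abs(o5), abs(o3), seed_sub)
    if (is.null(best) || lex_less(key, best$key)) {
      cand$key <- key
      best <- cand
    }
  }
  if (is.null(best)) {
    abort(sprintf("unassignable: no ungapped placement of '%s' on '%s' within offset bounds.",
                  sequence, mature_seq))
  }

  subs <- tibble(
    position = best$sub_pos,
    canonical = axis[best$ax[best$sub_pos]],
    observed = iso[best$sub_pos]
  )
  o5 <- best$o5; o3 <- best$o3
  cls <- if (o5 == 0L && o3 == 0L && nrow(subs) == 0L) "canonical"
    else if (o5 != 0L && o3 == 0L && nrow(subs) == 0L) "iso_5p"
    else if (o3 != 0L && o5 == 0L && nrow(subs) == 0L) "iso_3p"
    else if (o5 == 0L && o3 == 0L) "polymorphic"
    else "mixed"
  templated <- if (!best$any_ext) "templated"
    else if (best$ext_3p_mismatch) "non_templated"
    else if (best$ext_unknown) "unknown"
    else if (best$ext_any_mismatch) "non_templated"
    else "templated"
  tibble(
    five_prime_offset = o5,
    three_prime_offset = o3,
    n_substitutions = nrow(subs),
    substitutions = list(subs),
    variant_class = cls,
    templated = templated,
    seed_changing = o5 != 0L || any(subs$position >= 2L & subs$position <= 7L)
  )
}

# lexicographic comparison of equal-length numeric keys
lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Classify many isomiRs against a canonical catalog
#'
#' @param records Tibble with `sequence` and `parent` columns (one row per
#'   unique isomiR sequence).
#' @param catalog Canonical catalog tibble with `mirna_id`, `mature_seq`,
#'   `flank5`, `flank3` (see [read_mirna_catalog()] / [simulate_catalog()]).
#' @param ... Passed to [classify_isomir()].
#' @return `records` with the annotation columns of [classify_isomir()]
#'   appended. Rows whose parent is missing from the catalog, or that admit no
#'   placement, raise an error; use [parse_isomir_table()] for reject handling.
#' @export
classify_isomirs <- function(records, catalog, ...) {
  idx <- match(records$parent, catalog$mirna_id)
  if (anyNA(idx)) {
    abort(sprintf("parents absent from catalog: %s",
                  paste(unique(records$parent[is.na(idx)]), collapse = ", ")))
  }
  ann <- purrr::pmap(
    list(records$sequence, catalog$mature_seq[idx],
         catalog$flank5[idx], catalog$flank3[idx]),
    function(s, m, f5, f3) classify_isomir(s, m, f5, f3, ...)
  )
  dplyr::bind_cols(records, dplyr::bind_rows(ann))
}
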