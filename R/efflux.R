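# Cholesterol efflux (reverse cholesterol transport) quantification from
# scintillation CPM readings, and its correlation with the clinical score and
# selected feature abundances.

#' Total cholesterol efflux percentage
#'
#' 100 * medium / (medium + lysate): the fraction of labelled cholesterol
#' transferred from the macrophages into the medium acceptor.
#'
#' @param cpm_medium,cpm_lysate Beta counts per minute (medium aliquot and
#'   cell lysate); vectors recycle as usual.
#' @return Percentages in \[0, 100\].
#' @examples
#' total_efflux(250, 750)
#' @export
total_efflux <- function(cpm_medium, cpm_lysate) {
  if (any(cpm_medium < 0) || any(cpm_lysate < 0)) {
    abort("CPM values must be non-negative.")
  }
  if (any(cpm_medium + cpm_lysate == 0)) {
    abort("medium + lysate CPM must be positive.")
  }
  100 * cpm_medium / (cpm_medium + cpm_lysate)
}

#' Specific efflux percentage
#'
#' Sample total efflux minus the no-plasma blank's total efflux from the same
#' plate; slightly negative values are reported as-is.
#'
#' @param sample_total_pct,blank_total_pct Total efflux percentages.
#' @return Specific efflux (%).
#' @export
specific_efflux <- function(sample_total_pct, blank_total_pct) {
  sample_total_pct - blank_total_pct
}

#' Triplicate cleaning by the 1.15-SD rule
#'
#' Single pass over the three per-replicate total efflux percentages: any
#' value whose absolute difference from the triplicate mean is at least 1.15
#' sample standard deviations (n-1 denominator) is removed. The mean and SD
#' are not recomputed after removal. If the rule would leave fewer than two
#' values, all three are retained and the triplicate is flagged. With three
#' values the largest possible deviation is 2/sqrt(3) = 1.1547 SD, so at most
#' one value can ever be removed.
#'
#' @param values Numeric vector of length 3 (per-replicate total efflux %).
#' @param k SD multiplier (default 1.15).
#' @return Logical length-3 mask of retained replicates, with attribute
#'   `flagged` (TRUE when the rule was overridden to keep >= 2 values).
#' @examples
#' triplicate_clean(c(100, 102, 200))
#' @export
triplicate_clean <- function(values, k = 1.15) {
  if (length(values) != 3 || anyNA(values)) {
    abort("triplicate_clean expects exactly 3 finite values.")
  }
  s <- sd(values)
  if (s == 0) return(structure(rep(TRUE, 3), flagged = FALSE))
  keep <- abs(values - mean(values)) < k * s
  if (sum(keep) < 2) return(structure(rep(TRUE, 3), flagged = TRUE))
  structure(keep, flagged = FALSE)
}

#' Summarise an efflux plate to per-sample efflux values
#'
#' Computes per-replicate total efflux, cleans each triplicate by the 1.15-SD
#' rule, averages the retained replicates, and subtracts the plate blank's
#' total efflux to give specific efflux.
#'
#' @param plate Tibble with `sample_id`, `replicate_index`, `cpm_medium`,
#'   `cpm_lysate`, `is_blank` (exactly one blank row).
#' @param k SD multiplier for [triplicate_clean()].
#' @return Tibble: `sample_id`, `n_replicates_kept`, `flagged`,
#'   `total_efflux_pct` (mean of cleaned replicates),
#'   `total_efflux_pct_raw` (mean before cleaning), `specific_efflux_pct`.
#' @export
summarize_efflux <- function(plate, k = 1.15) {
  need <- c("sample_id", "replicate_index", "cpm_medium", "cpm_lysate", "is_blank")
  if (!all(need %in% names(plate))) {
    abort(sprintf("plate must have columns: %s", paste(need, collapse = ", ")))
  }
  blank <- plate %>% filter(.data$is_blank)
  if (nrow(blank) != 1) abort("plate must contain exactly one blank row.")
  blank_tot <- total_efflux(blank$cpm_medium, blank$cpm_lysate)

  plate %>%
    filter(!.data$is_blank) %>%
    mutate(tot = total_efflux(.data$cpm_medium, .data$cpm_lysate)) %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_replicates = dplyr::n(),
      total_efflux_pct_raw = mean(.data$tot),
      total_efflux_pct = {
        mask <- triplicate_clean(.data$tot, k = k)
        mean(.data$tot[mask])
      },
      n_replicates_kept = sum(triplicate_clean(.data$tot, k = k)),
      flagged = attr(triplicate_clean(.data$tot, k = k), "flagged"),
      .groups = "drop"
    ) %>%
    mutate(specific_efflux_pct = specific_efflux(.data$total_efflux_pct, blank_tot)) %>%
    select("sample_id", "n_replicates", "n_replicates_kept", "flagged",
           "total_efflux_pct_raw", "total_efflux_pct", "specific_efflux_pct")
}

#' Correlate specific efflux with the clinical score and feature abundances
#'
#' Pearson correlation (with the two-sided test p-value) between per-sample
#' specific efflux and (a) the clinical score and (b) each requested
#' feature's RPM profile.
#'
#' @param efflux Output of [summarize_efflux()].
#' @param cohort Tibble with `sample_id` and `score`.
#' @param feature_rpm Optional RPM count table; correlations are computed for
#'   each of `features` (default: all rows).
#' @param features Character vector of feature IDs to correlate.
#' @return Tibble: `variable`, `r`, `p_value`, `n`.
#' @export
efflux_associations <- function(efflux, cohort, feature_rpm = NULL,
                                features = NULL) {
  joined <- efflux %>%
    dplyr::inner_join(cohort %>% select("sample_id", "score"), by = "sample_id")
  if (nrow(joined) < 4) {
    abort("need at least 4 samples with both efflux and score.")
  }
  pearson_row <- function(label, x, y) {
    ok <- !is.na(x) & !is.na(y)
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble(variable = label, r = unname(ct$estimate),
           p_value = ct$p.value, n = sum(ok))
  }
  out <- pearson_row("score", joined$specific_efflux_pct, joined$score)
  if (!is.null(feature_rpm)) {
    features <- features %||% feature_rpm$feature_id
    m <- count_matrix(feature_rpm)
    feats <- intersect(features, rownames(m))
    for (f in feats) {
      v <- m[f, joined$sample_id]
      out <- bind_rows(out,
                       pearson_row(f, joined$specific_efflux_pct, as.numeric(v)))
    }
  }
  out
}
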