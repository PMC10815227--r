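# isomiR-versus-parent-miRNA superiority comparison.

#' Compare candidate isomiRs against their parent miRNA
#'
#' For every candidate isomiR, compares the isomiR-level screen record with
#' the aggregated parent miRNA's record on the same cohort and cutoff:
#' stronger correlation (|rho|), lower adjusted p-value, larger dynamic range
#' and higher ROC-AUC. An isomiR is `superior` when all four hold; it is
#' `isomir_only` when it is significant while its parent is not. A parent
#' with no adjusted p-value (never entered the correction family) counts as
#' p_adj = 1; an undefined dynamic range never counts as larger; parents
#' missing from the miRNA screen (e.g. failed the abundance filter) have
#' their rho/AUC/range computed ad hoc from `mirna_rpm` when supplied,
#' otherwise those comparisons are NA and cannot support superiority.
#'
#' @param isomir_screen,mirna_screen `isomir_screen` objects from
#'   [screen_associations()] run on the same cohort.
#' @param parent_map Tibble with `feature_id` (isomiR) and `parent` columns.
#' @param mirna_rpm Optional miRNA-level RPM table used to compute stats for
#'   parents absent from `mirna_screen`.
#' @return Tibble: `isomir_id`, `parent_id`, per-level rho/p_adj/auc/range
#'   columns, `stronger_rho`, `lower_padj`, `larger_dynamic_range`,
#'   `higher_auc`, `superior`, `isomir_only`.
#' @export
compare_isomir_vs_parent <- function(isomir_screen, mirna_screen, parent_map,
                                     mirna_rpm = NULL) {
  stopifnot(inherits(isomir_screen, "isomir_screen"),
            inherits(mirna_screen, "isomir_screen"))
  iso <- isomir_screen$results %>% filter(.data$candidate)
  if (nrow(iso) == 0) {
    return(tibble(
      isomir_id = character(), parent_id = character(),
      rho_isomir = numeric(), rho_mirna = numeric(),
      p_adj_isomir = numeric(), p_adj_mirna = numeric(),
      auc_isomir = numeric(), auc_mirna = numeric(),
      dynamic_range_isomir = numeric(), dynamic_range_mirna = numeric(),
      stronger_rho = logical(), lower_padj = logical(),
      larger_dynamic_range = logical(), higher_auc = logical(),
      superior = logical(), isomir_only = logical()
    ))
  }
  mir <- mirna_screen$results
  pm <- parent_map %>% select("feature_id", "parent")
  iso <- iso %>% left_join(pm, by = "feature_id")

  parent_row <- function(p) {
    hit <- mir[mir$feature_id == p, ]
    if (nrow(hit) == 1) {
      tibble(rho_mirna = hit$rho,
             p_adj_mirna = ifelse(is.na(hit$p_adj), 1, hit$p_adj),
             auc_mirna = hit$auc,
             dynamic_range_mirna = hit$dynamic_range,
             parent_significant = hit$significant)
    } else if (!is.null(mirna_rpm) && p %in% mirna_rpm$feature_id) {
      v <- as.numeric(count_matrix(mirna_rpm)[p, ])
      labels <- stratify_high_low(mirna_screen$scores,
                                  mirna_screen$params$cutoff)
      auc <- if (length(unique(labels)) == 2) {
        roc_auc_ci(v, labels)$auc
      } else NA_real_
      tibble(rho_mirna = spearman_rho(v, mirna_screen$scores),
             p_adj_mirna = 1, auc_mirna = auc,
             dynamic_range_mirna = dynamic_range(values = v),
             parent_significant = FALSE)
    } else {
      tibble(rho_mirna = NA_real_, p_adj_mirna = 1, auc_mirna = NA_real_,
             dynamic_range_mirna = NA_real_, parent_significant = FALSE)
    }
  }
  pr <- purrr::map_dfr(iso$parent, parent_row)

  tibble(
    isomir_id = iso$feature_id,
    parent_id = iso$parent,
    rho_isomir = iso$rho, rho_mirna = pr$rho_mirna,
    p_adj_isomir = ifelse(is.na(iso$p_adj), 1, iso$p_adj),
    p_adj_mirna = pr$p_adj_mirna,
    auc_isomir = iso$auc, auc_mirna = pr$auc_mirna,
    dynamic_range_isomir = iso$dynamic_range,
    dynamic_range_mirna = pr$dynamic_range_mirna
  ) %>%
    mutate(
      stronger_rho = !is.na(.data$rho_mirna) &
        abs(.data$rho_isomir) > abs(.data$rho_mirna),
      lower_padj = .data$p_adj_isomir < .data$p_adj_mirna,
      larger_dynamic_range = !is.na(.data$dynamic_range_isomir) &
        !is.na(.data$dynamic_range_mirna) &
        .data$dynamic_range_isomir > .data$dynamic_range_mirna,
      higher_auc = !is.na(.data$auc_isomir) & !is.na(.data$auc_mirna) &
        .data$auc_isomir > .data$auc_mirna,
      superior = .data$stronger_rho & .data$lower_padj &
        .data$larger_dynamic_range & .data$higher_auc,
      isomir_only = iso$significant & !pr$parent_significant
    )
}
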