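# ggplot2 views of screens, runs and efflux results.

#' Plot a correlation screen
#'
#' Scatter of Spearman rho against the BH-adjusted permutation p-value
#' (-log10), highlighting candidates and significant features. Features
#' without an adjusted p-value (candidates-only family) are drawn at p = 1.
#'
#' @param object An `isomir_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isomir_screen <- function(object, ...) {
  r <- object$results %>%
    mutate(
      p_plot = pmax(ifelse(is.na(.data$p_adj), 1, .data$p_adj),
                    1 / (2 * object$params$n_perm)),
      status = dplyr::case_when(
        .data$significant ~ "significant",
        .data$candidate ~ "candidate",
        TRUE ~ "screened"
      )
    )
  thr <- object$params$rho_threshold
  ggplot2::ggplot(r, ggplot2::aes(x = .data$rho,
                                  y = -log10(.data$p_plot),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(
      screened = "grey70", candidate = "#2c7fb8", significant = "#d95f02")) +
    ggplot2::labs(
      x = "Spearman rho (abundance vs score)",
      y = "-log10 adjusted permutation p",
      colour = NULL,
      title = sprintf("%s-level correlation screen", object$level)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run funnel
#'
#' Bar chart of feature counts surviving each sequential filtration stage,
#' per level (log10 y-scale since the isomiR funnel typically spans orders
#' of magnitude).
#'
#' @param object An `isomirome_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isomirome_run <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$stage, y = pmax(.data$n, 0.5),
                               fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "features (log scale)", fill = NULL,
                  title = "Sequential filtration funnel") +
    ggplot2::theme_minimal()
}

#' Plot specific efflux against the clinical score
#'
#' @param efflux Output of [summarize_efflux()].
#' @param cohort Tibble with `sample_id` and `score`.
#' @return A ggplot with a linear trend line.
#' @export
plot_efflux_score <- function(efflux, cohort) {
  d <- efflux %>%
    dplyr::inner_join(cohort %>% select("sample_id", "score"),
                      by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  y = .data$specific_efflux_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#d95f02") +
    ggplot2::labs(x = "clinical risk percentile",
                  y = "specific cholesterol efflux (%)",
                  title = "Reverse cholesterol transport vs risk score") +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of one feature
#'
#' Empirical ROC of a marker for the high/low stratification, annotated with
#' the AUC and its DeLong confidence interval.
#'
#' @param values Numeric marker values.
#' @param labels Logical labels (TRUE = high class).
#' @return A ggplot.
#' @export
plot_roc <- function(values, labels) {
  stats <- roc_auc_ci(values, labels)
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    tibble(tpr = mean(values[labels] >= t), fpr = mean(values[!labels] >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC-AUC %.2f (95%% CI %.2f-%.2f)%s", stats$auc,
                      stats$auc_ci_low, stats$auc_ci_high,
                      if (isTRUE(stats$discriminative)) " *" else "")
    ) +
    ggplot2::theme_minimal()
}
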