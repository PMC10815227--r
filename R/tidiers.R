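# broom-style accessors for screen and run objects.

#' Tidy a correlation screen
#'
#' @param x An `isomir_screen` from [screen_associations()].
#' @param ... Unused.
#' @return The per-feature results tibble (one row per screened feature).
#' @export
tidy.isomir_screen <- function(x, ...) {
  x$results
}

#' One-row summary of a correlation screen
#'
#' @param x An `isomir_screen`.
#' @param ... Unused.
#' @return Tibble: `level`, `n_features`, `n_candidates`, `n_significant`,
#'   `n_discriminative`, `n_excluded`, `n_samples`, `n_perm`.
#' @export
glance.isomir_screen <- function(x, ...) {
  r <- x$results
  tibble(
    level = x$level,
    n_features = nrow(r),
    n_candidates = sum(r$candidate),
    n_significant = sum(r$significant),
    n_discriminative = sum(r$discriminative, na.rm = TRUE),
    n_excluded = nrow(x$excluded),
    n_samples = x$n_samples,
    n_perm = x$params$n_perm
  )
}

#' Tidy a pipeline run
#'
#' @param x An `isomirome_run` from [run_analysis()] / [run_pipeline()].
#' @param ... Unused.
#' @return The funnel tibble in long form: `level`, `stage`, `n`; stages are
#'   ordered total -> abundance -> candidate -> significant ->
#'   discriminative.
#' @export
tidy.isomirome_run <- function(x, ...) {
  x$funnel %>%
    tidyr::pivot_longer(-"level", names_to = "stage", values_to = "n") %>%
    mutate(stage = factor(sub("^n_", "", .data$stage),
                          levels = c("total", "passed_abundance",
                                     "candidates", "significant",
                                     "discriminative")))
}

#' One-row summary of a pipeline run
#'
#' @param x An `isomirome_run`.
#' @param ... Unused.
#' @return Tibble with the funnel endpoints and the headline counts
#'   (superior isomiRs, isomiR-only findings, seed-changing isomiR-only
#'   findings, libraries removed).
#' @export
glance.isomirome_run <- function(x, ...) {
  f <- x$funnel
  tibble(
    n_libraries = nrow(x$cohort),
    n_libraries_removed = nrow(x$libraries_removed),
    n_isomirs_significant = f$n_significant[f$level == "isomir"],
    n_mirnas_significant = f$n_significant[f$level == "mirna"],
    n_superior_isomirs = x$n_superior_isomirs,
    n_isomir_only = x$n_isomir_only,
    n_seed_changing_isomir_only = x$n_seed_changing_isomir_only
  )
}
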