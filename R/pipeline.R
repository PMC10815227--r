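# End-to-end orchestration: QC gates -> RPM -> aggregation -> abundance
# filter -> correlation screen (both levels) -> superiority -> efflux, with a
# funnel report and a run log.

#' Pipeline configuration
#'
#' Paths to the four input files plus every analysis threshold. Defaults are
#' the screen's standard values: abundance filter mean > 5 RPM and max > 50
#' RPM, candidate cutoff |rho| >= 0.55, 10,000 permutations, alpha = 0.05 on
#' BH-adjusted p-values, and the 75th percentile as the high/low risk cutoff.
#'
#' @param isomir_tsv,sample_tsv Paths to the isomiR count TSV and sample
#'   metadata TSV (required).
#' @param catalog_fasta Path to the mature miRNA FASTA (required).
#' @param precursor_fasta Optional precursor-context FASTA.
#' @param efflux_tsv Optional efflux plate TSV; when NULL the efflux stage is
#'   skipped.
#' @param min_mean_rpm,min_max_rpm Abundance filter thresholds.
#' @param rho_threshold Candidate cutoff on |Spearman rho|.
#' @param n_perm Number of score shufflings for the permutation test.
#' @param alpha Significance level on adjusted p-values.
#' @param cutoff High/low risk score percentile cutoff.
#' @param min_cor Inter-library correlation floor for the QC outlier scan.
#' @param p_family BH family: `"candidates"` (default, the literal screen-then-correct ordering) or `"filtered"`.
#' @param add_one Use the (count+1)/(n_perm+1) permutation p estimator.
#' @param strict_qc Abort (instead of removing and logging) when any QC gate
#'   fails.
#' @param rng_seed Seed for the shared permutation stream.
#' @return List of class `isomirome_config`.
#' @export
pipeline_config <- function(isomir_tsv, sample_tsv, catalog_fasta,
                            precursor_fasta = NULL, efflux_tsv = NULL,
                            min_mean_rpm = 5, min_max_rpm = 50,
                            rho_threshold = 0.55, n_perm = 10000L,
                            alpha = 0.05, cutoff = 75, min_cor = 0.6,
                            p_family = "candidates", add_one = FALSE,
                            strict_qc = FALSE, rng_seed = 1L) {
  if (min_mean_rpm <= 0 || min_max_rpm <= 0 || rho_threshold <= 0) {
    abort("config: thresholds must be positive.")
  }
  if (alpha <= 0 || alpha >= 1) abort("config: alpha must lie in (0, 1).")
  structure(list(
    isomir_tsv = isomir_tsv, sample_tsv = sample_tsv,
    catalog_fasta = catalog_fasta, precursor_fasta = precursor_fasta,
    efflux_tsv = efflux_tsv, min_mean_rpm = min_mean_rpm,
    min_max_rpm = min_max_rpm, rho_threshold = rho_threshold,
    n_perm = as.integer(n_perm), alpha = alpha, cutoff = cutoff,
    min_cor = min_cor, p_family = p_family, add_one = add_one,
    strict_qc = strict_qc, rng_seed = as.integer(rng_seed)
  ), class = "isomirome_config")
}

#' Run the full screen from input files
#'
#' Reads the catalog, isomiR table, sample table and (optionally) the efflux
#' plate, then calls [run_analysis()]. See that function for the stage order
#' and the returned object.
#'
#' @param config An [pipeline_config()] object.
#' @param output_dir Optional directory; when given, all output tables, the
#'   funnel JSON and the run log are written there via [write_run_outputs()].
#' @return An `isomirome_run` object.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "isomirome_config"))
  catalog <- read_mirna_catalog(config$catalog_fasta, config$precursor_fasta)
  parsed <- parse_isomir_table(config$isomir_tsv, catalog)
  cohort <- read_sample_table(config$sample_tsv)
  efflux <- if (!is.null(config$efflux_tsv)) read_efflux_table(config$efflux_tsv)
  run <- run_analysis(parsed$counts, cohort, efflux = efflux,
                      records = parsed$records, params = config)
  run$rejects <- parsed$rejects
  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

#' Run the full screen on in-memory tables
#'
#' Stage order: hemolysis gate (delta-Ct < 7) -> library outlier removal
#' (detection-rate Tukey fence OR inter-library correlation floor) -> RPM
#' normalisation -> aggregation to miRNA level -> dual abundance filter (both
#' levels) -> Spearman screen with shared-stream permutation p-values and BH
#' correction (both levels) -> ROC-AUC discrimination -> isomiR-vs-parent
#' superiority -> optional efflux associations. Every sample removal is
#' logged with its reason; all randomness derives from `params$rng_seed`.
#'
#' @param counts IsomiR-level raw count table (`feature_id`, `parent`, one
#'   column per library).
#' @param cohort Sample table (`sample_id`, `score`, `ct_mir23a`,
#'   `ct_mir451a`).
#' @param efflux Optional efflux plate tibble.
#' @param records Optional annotation tibble (from [parse_isomir_table()] or
#'   [classify_isomirs()]) carrying `isomir_id` and `seed_changing`; enables
#'   the seed-change counts in the funnel.
#' @param params An [pipeline_config()] (file paths may be empty) or a list
#'   of the same threshold fields.
#' @return Object of class `isomirome_run`: list with `funnel` (tibble),
#'   `qc`, `screens` (isomir/mirna `isomir_screen`s), `abundance`,
#'   `superiority`, `efflux`, `log`, `params`. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
run_analysis <- function(counts, cohort, efflux = NULL, records = NULL,
                         params = NULL) {
  p <- default_params(params)
  log <- character(0)
  say <- function(fmt, ...) sprintf(fmt, ...)

  assert_count_table(counts, raw = TRUE)
  sc <- sample_cols(counts)
  if (!setequal(sc, cohort$sample_id)) {
    abort("count table libraries and cohort sample_ids disagree.")
  }
  cohort <- cohort[match(sc, cohort$sample_id), ]

  # -- QC: hemolysis gate ----------------------------------------------------
  hemo <- hemolysis_check(cohort)
  removed <- tibble(sample_id = character(), reason = character())
  if (any(!hemo$hemolysis_pass)) {
    bad <- hemo$sample_id[!hemo$hemolysis_pass]
    msg <- say("hemolysis gate: delta-Ct >= 7 for %s", paste(bad, collapse = ", "))
    if (p$strict_qc) abort(msg)
    log <- c(log, msg)
    removed <- bind_rows(removed, tibble(sample_id = bad, reason = "hemolysis"))
    counts <- counts[, !names(counts) %in% bad]
    cohort <- cohort[!cohort$sample_id %in% bad, ]
  }

  # -- QC: library outlier scan ----------------------------------------------
  scan <- library_outlier_scan(counts, min_cor = p$min_cor)
  if (any(scan$outlier)) {
    bad <- scan$sample_id[scan$outlier]
    for (b in bad) {
      row <- scan[scan$sample_id == b, ]
      msg <- say(
        "library outlier: %s removed (detects %d of the >=5-library common set vs cohort median %d; median inter-library rho %.2f)",
        b, row$n_in_common5, as.integer(median(scan$n_in_common5)),
        row$median_intercorrelation)
      if (p$strict_qc) abort(msg)
      log <- c(log, msg)
    }
    removed <- bind_rows(removed, tibble(sample_id = bad, reason = "library_outlier"))
    counts <- counts[, !names(counts) %in% bad]
    cohort <- cohort[!cohort$sample_id %in% bad, ]
  }
  if (nrow(cohort) < 4) abort("fewer than 4 libraries survive QC.")
  log <- c(log, say("%d of %d libraries retained after QC", nrow(cohort),
                    nrow(hemo)))

  # -- normalisation, aggregation, abundance filter --------------------------
  iso_rpm <- rpm_normalize(counts)
  mir_counts <- aggregate_mirna(counts)
  mir_rpm <- rpm_normalize(mir_counts)
  iso_ab <- abundance_summary(iso_rpm, p$min_mean_rpm, p$min_max_rpm)
  mir_ab <- abundance_summary(mir_rpm, p$min_mean_rpm, p$min_max_rpm)
  iso_keep <- iso_rpm %>% filter(.data$feature_id %in%
                                   iso_ab$feature_id[iso_ab$passed_filter])
  mir_keep <- mir_rpm %>% filter(.data$feature_id %in%
                                   mir_ab$feature_id[mir_ab$passed_filter])
  log <- c(log,
           say("abundance filter (mean > %g RPM, max > %g RPM): %d of %d isomiRs, %d of %d miRNAs retained",
               p$min_mean_rpm, p$min_max_rpm, nrow(iso_keep), nrow(iso_rpm),
               nrow(mir_keep), nrow(mir_rpm)))

  # -- correlation screens ---------------------------------------------------
  screen_args <- list(scores = cohort$score, rho_threshold = p$rho_threshold,
                      n_perm = p$n_perm, seed = p$rng_seed, alpha = p$alpha,
                      cutoff = p$cutoff, p_family = p$p_family,
                      add_one = p$add_one)
  iso_screen <- do.call(screen_associations,
                        c(list(iso_keep, level = "isomir"), screen_args))
  mir_screen <- do.call(screen_associations,
                        c(list(mir_keep, level = "mirna"), screen_args))
  log <- c(log, iso_screen$notes, mir_screen$notes)

  # -- superiority -----------------------------------------------------------
  parent_map <- counts %>% select("feature_id", "parent")
  sup <- compare_isomir_vs_parent(iso_screen, mir_screen, parent_map,
                                  mirna_rpm = mir_rpm)
  if (!is.null(records) && "seed_changing" %in% names(records)) {
    sup$seed_changing <- records$seed_changing[
      match(sup$isomir_id, records$isomir_id)]
  } else {
    sup$seed_changing <- NA
  }

  # -- efflux (optional) -----------------------------------------------------
  efflux_out <- NULL
  if (!is.null(efflux)) {
    ef_sum <- summarize_efflux(efflux)
    ef_sum <- ef_sum %>% filter(.data$sample_id %in% cohort$sample_id)
    sig_iso <- iso_screen$results$feature_id[iso_screen$results$significant]
    ef_assoc <- efflux_associations(ef_sum, cohort,
                                    feature_rpm = iso_rpm,
                                    features = sig_iso)
    efflux_out <- list(per_sample = ef_sum, associations = ef_assoc)
    log <- c(log, say("efflux stage: %d samples, %d feature correlations",
                      nrow(ef_sum), nrow(ef_assoc) - 1L))
  } else {
    log <- c(log, "efflux stage skipped: no plate supplied")
  }

  # -- funnel ----------------------------------------------------------------
  funnel <- bind_rows(
    funnel_row("isomir", nrow(iso_rpm), iso_ab, iso_screen),
    funnel_row("mirna", nrow(mir_rpm), mir_ab, mir_screen)
  )
  n_sup <- sum(sup$superior, na.rm = TRUE)
  n_io <- sum(sup$isomir_only, na.rm = TRUE)
  n_scio <- sum(sup$isomir_only & sup$seed_changing, na.rm = TRUE)

  structure(list(
    funnel = funnel,
    n_superior_isomirs = n_sup,
    n_isomir_only = n_io,
    n_seed_changing_isomir_only = n_scio,
    libraries_removed = removed,
    qc = list(hemolysis = hemo, outlier_scan = scan),
    abundance = list(isomir = iso_ab, mirna = mir_ab),
    screens = list(isomir = iso_screen, mirna = mir_screen),
    superiority = sup,
    efflux = efflux_out,
    cohort = cohort,
    log = log,
    params = p
  ), class = "isomirome_run")
}

funnel_row <- function(level, n_total, ab, screen) {
  r <- screen$results
  tibble(
    level = level,
    n_total = n_total,
    n_passed_abundance = sum(ab$passed_filter),
    n_candidates = sum(r$candidate),
    n_significant = sum(r$significant),
    n_discriminative = sum(r$discriminative, na.rm = TRUE)
  )
}

default_params <- function(params) {
  base <- list(min_mean_rpm = 5, min_max_rpm = 50, rho_threshold = 0.55,
               n_perm = 10000L, alpha = 0.05, cutoff = 75, min_cor = 0.6,
               p_family = "candidates", add_one = FALSE, strict_qc = FALSE,
               rng_seed = 1L)
  if (is.null(params)) return(base)
  modifyList(base, params[intersect(names(params), names(base))])
}

#' @export
print.isomirome_run <- function(x, ...) {
  cat("<isomirome_run>\n")
  cat(sprintf("  libraries removed by QC: %s\n",
              if (nrow(x$libraries_removed) == 0) "none" else
                paste(x$libraries_removed$sample_id, collapse = ", ")))
  print(x$funnel)
  cat(sprintf("  superior isomiRs: %d; isomiR-only: %d (seed-changing: %d)\n",
              x$n_superior_isomirs, x$n_isomir_only,
              x$n_seed_changing_isomir_only))
  invisible(x)
}

#' Write all run outputs to a directory
#'
#' Emits `qc_report.tsv`, `abundance_isomir.tsv`, `abundance_mirna.tsv`,
#' `assoc_isomir.tsv`, `assoc_mirna.tsv`, `superiority.tsv`, `efflux.tsv`
#' (when the stage ran), `funnel.json` and `run.log`. The association tables
#' mirror the screen's headline columns, with the ROC column shown as "ND"
#' for non-discriminative features.
#'
#' @param run An `isomirome_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qc <- run$qc$outlier_scan %>%
    left_join(run$qc$hemolysis %>%
                select("sample_id", "delta_ct", "hemolysis_pass"),
              by = "sample_id")
  readr::write_tsv(qc, file.path(dir, "qc_report.tsv"))
  readr::write_tsv(run$abundance$isomir, file.path(dir, "abundance_isomir.tsv"))
  readr::write_tsv(run$abundance$mirna, file.path(dir, "abundance_mirna.tsv"))
  assoc_tsv <- function(screen, path) {
    screen$results %>%
      mutate(roc_auc = ifelse(.data$discriminative %in% TRUE,
                              sprintf("%.2f (%.2f-%.2f)", .data$auc,
                                      .data$auc_ci_low, .data$auc_ci_high),
                              "ND")) %>%
      readr::write_tsv(path)
  }
  assoc_tsv(run$screens$isomir, file.path(dir, "assoc_isomir.tsv"))
  assoc_tsv(run$screens$mirna, file.path(dir, "assoc_mirna.tsv"))
  readr::write_tsv(run$superiority, file.path(dir, "superiority.tsv"))
  if (!is.null(run$efflux)) {
    readr::write_tsv(run$efflux$per_sample, file.path(dir, "efflux.tsv"))
    readr::write_tsv(run$efflux$associations,
                     file.path(dir, "efflux_associations.tsv"))
  }
  jsonlite::write_json(
    list(funnel = run$funnel,
         n_superior_isomirs = run$n_superior_isomirs,
         n_isomir_only = run$n_isomir_only,
         n_seed_changing_isomir_only = run$n_seed_changing_isomir_only,
         libraries_removed = run$libraries_removed$sample_id),
    file.path(dir, "funnel.json"), auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}
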