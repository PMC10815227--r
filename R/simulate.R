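# Seeded synthetic cohort generator.
#
# Emulates the inputs of a small plasma small RNA-seq biomarker study: a
# canonical miRNA catalog with precursor context, a per-parent isomiR
# repertoire, a cohort table (clinical score on a 0-99 percentile scale plus
# hemolysis qPCR Cts), an isomiR count matrix with planted score-abundance
# associations, and a cholesterol-efflux plate. All outputs are deterministic
# given `rng_seed`.

#' Simulation configuration
#'
#' Defaults encode the study shape the generator emulates: 13 libraries
#' (roughly 6 above and 7 below the 75th risk percentile), one degenerate
#' outlier library, two planted miRNA-level signals, one planted
#' "isomiR-correlates-but-parent-does-not" scenario with a seed-changing
#' variant, and an efflux plate whose specific efflux is inversely correlated
#' with the score (population Pearson r = -0.577) with one aberrant replicate
#' in 5 of 13 samples.
#'
#' @param n_samples Number of libraries (>= 4).
#' @param n_mirnas Number of canonical miRNAs in the catalog.
#' @param isomirs_per_mirna Integer length-2 range: isomiRs per parent
#'   (including the canonical sequence).
#' @param n_planted_mirna Number of miRNAs with a planted whole-miRNA score
#'   association (all isomiRs coupled to the score; the dominant "lead"
#'   isomiR at full strength).
#' @param n_planted_isomir_only Number of parents where one seed-changing
#'   isomiR is planted positive while a compensating sibling keeps the
#'   aggregated parent flat.
#' @param effect_rho Target population Spearman correlation of planted
#'   features with the score (0 < rho <= 1).
#' @param sib_coupling Fraction of `effect_rho` given to the non-lead isomiRs
#'   of a planted miRNA. The default of 1 makes the whole-miRNA signal
#'   coherent (every isomiR of the parent tracks the score, as co-produced
#'   variants of one transcript do), so the aggregated parent is at least as
#'   correlated as any single isomiR; values < 1 weaken the siblings.
#' @param lead_share Abundance share of the lead isomiR within a planted
#'   parent.
#' @param depth_range Length-2 range of per-library total read counts.
#' @param dispersion Log-normal sd of the per-feature per-sample abundance
#'   noise (count overdispersion on top of Poisson sampling).
#' @param outlier_library Inject one degenerate library (70% of otherwise
#'   ubiquitous features zeroed)?
#' @param outlier_zero_frac Fraction of common features zeroed in the outlier
#'   library.
#' @param n_hemolytic Number of cohort samples failing the hemolysis gate
#'   (delta-Ct >= 7).
#' @param high_frac Fraction of samples with score >= 75.
#' @param efflux_r Target population Pearson correlation between specific
#'   efflux and the score.
#' @param efflux_mean,efflux_sd Mean and sd of specific efflux (%).
#' @param blank_efflux Total efflux (%) of the no-plasma blank.
#' @param replicate_sd Replicate-to-replicate sd of total efflux (%).
#' @param aberrant_frac Fraction of samples given one aberrant efflux
#'   replicate (offset `aberrant_shift` %).
#' @param aberrant_shift Absolute offset (%) of an aberrant replicate.
#' @param rng_seed Integer seed; all outputs are reproducible under it.
#' @return A validated list of class `isomirome_sim_config`.
#' @export
simulation_config <- function(n_samples = 13L,
                              n_mirnas = 80L,
                              isomirs_per_mirna = c(3L, 8L),
                              n_planted_mirna = 2L,
                              n_planted_isomir_only = 1L,
                              effect_rho = 0.9,
                              sib_coupling = 1,
                              lead_share = 0.7,
                              depth_range = c(1e6, 3e6),
                              dispersion = 0.7,
                              outlier_library = TRUE,
                              outlier_zero_frac = 0.7,
                              n_hemolytic = 0L,
                              high_frac = 6 / 13,
                              efflux_r = -0.577,
                              efflux_mean = 12,
                              efflux_sd = 3,
                              blank_efflux = 3,
                              replicate_sd = 0.25,
                              aberrant_frac = 5 / 13,
                              aberrant_shift = 6,
                              rng_seed = 890L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_mirnas = as.integer(n_mirnas),
    isomirs_per_mirna = as.integer(isomirs_per_mirna),
    n_planted_mirna = as.integer(n_planted_mirna),
    n_planted_isomir_only = as.integer(n_planted_isomir_only),
    effect_rho = effect_rho, sib_coupling = sib_coupling,
    lead_share = lead_share, depth_range = depth_range,
    dispersion = dispersion, outlier_library = isTRUE(outlier_library),
    outlier_zero_frac = outlier_zero_frac,
    n_hemolytic = as.integer(n_hemolytic), high_frac = high_frac,
    efflux_r = efflux_r, efflux_mean = efflux_mean, efflux_sd = efflux_sd,
    blank_efflux = blank_efflux, replicate_sd = replicate_sd,
    aberrant_frac = aberrant_frac, aberrant_shift = aberrant_shift,
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_samples < 4L) abort("config: n_samples must be >= 4.")
  if (cfg$n_mirnas < 1L) abort("config: n_mirnas must be >= 1.")
  if (length(cfg$isomirs_per_mirna) != 2L ||
      any(cfg$isomirs_per_mirna < 1L) ||
      cfg$isomirs_per_mirna[1] > cfg$isomirs_per_mirna[2]) {
    abort("config: isomirs_per_mirna must be an increasing length-2 range >= 1.")
  }
  if (!is_scalar_number(cfg$effect_rho) || cfg$effect_rho <= 0 || cfg$effect_rho > 1) {
    abort("config: effect_rho must lie in (0, 1].")
  }
  if (any(cfg$depth_range <= 0) || cfg$depth_range[1] > cfg$depth_range[2]) {
    abort("config: depth_range must be a positive increasing range.")
  }
  if (cfg$n_planted_mirna + cfg$n_planted_isomir_only > cfg$n_mirnas) {
    abort("config: more planted scenarios than miRNAs.")
  }
  if (cfg$n_hemolytic >= cfg$n_samples) {
    abort("config: n_hemolytic must leave at least one clean sample.")
  }
  structure(cfg, class = "isomirome_sim_config")
}

as_sim_config <- function(config) {
  if (inherits(config, "isomirome_sim_config")) return(config)
  do.call(simulation_config, config)
}

RNA_BASES <- c("A", "C", "G", "U")

#' Simulate a canonical miRNA catalog
#'
#' Mature sequences are uniform random RNA of length 20-24 nt with an 8-nt
#' precursor context on each side (used for templated extensions).
#'
#' @param config A [simulation_config()].
#' @return Tibble: `mirna_id`, `mature_seq`, `flank5`, `flank3`.
#' @export
simulate_catalog <- function(config = simulation_config()) {
  config <- as_sim_config(config)
  withr::with_seed(child_seed(config$rng_seed, 1L), {
    n <- config$n_mirnas
    lens <- sample(20:24, n, replace = TRUE)
    rand_seq <- function(k) paste(sample(RNA_BASES, k, replace = TRUE), collapse = "")
    tibble(
      mirna_id = sprintf("syn-miR-%03d", seq_len(n)),
      mature_seq = vapply(lens, rand_seq, character(1)),
      flank5 = vapply(rep(8L, n), rand_seq, character(1)),
      flank3 = vapply(rep(8L, n), rand_seq, character(1))
    )
  })
}

# single-operation variant constructors; each returns sequence + truth labels
apply_variant_op <- function(op, mature, flank5, flank3) {
  L <- nchar(mature)
  sub_at <- function(seq, pos) {
    old <- substr(seq, pos, pos)
    new <- sample(setdiff(RNA_BASES, old), 1)
    paste0(substr(seq, 1, pos - 1), new, substr(seq, pos + 1, nchar(seq)))
  }
  switch(op,
    trim5_1 = list(seq = substr(mature, 2, L), class = "iso_5p", seed = TRUE),
    trim5_2 = list(seq = substr(mature, 3, L), class = "iso_5p", seed = TRUE),
    ext5_1 = list(seq = paste0(substr(flank5, 8, 8), mature),
                  class = "iso_5p", seed = TRUE),
    ext5_2 = list(seq = paste0(substr(flank5, 7, 8), mature),
                  class = "iso_5p", seed = TRUE),
    trim3_1 = list(seq = substr(mature, 1, L - 1), class = "iso_3p", seed = FALSE),
    trim3_2 = list(seq = substr(mature, 1, L - 2), class = "iso_3p", seed = FALSE),
    ext3_1 = list(seq = paste0(mature, substr(flank3, 1, 1)),
                  class = "iso_3p", seed = FALSE),
    ext3_2 = list(seq = paste0(mature, substr(flank3, 1, 2)),
                  class = "iso_3p", seed = FALSE),
    nta_A = list(seq = paste0(mature, "A"), class = "iso_3p", seed = FALSE),
    nta_U = list(seq = paste0(mature, "U"), class = "iso_3p", seed = FALSE),
    sub = {
      pos <- sample(seq_len(L), 1)
      list(seq = sub_at(mature, pos), class = "polymorphic",
           seed = pos >= 2 && pos <= 7)
    },
    sub_seed = {
      pos <- sample(2:7, 1)
      list(seq = sub_at(mature, pos), class = "polymorphic", seed = TRUE)
    },
    mixed_5p = list(seq = paste0(substr(mature, 2, L), sample(c("A", "U"), 1)),
                    class = "mixed", seed = TRUE),
    mixed_3p = {
      pos <- sample(8:(L - 2), 1)
      list(seq = sub_at(substr(mature, 1, L - 1), pos), class = "mixed",
           seed = FALSE)
    },
    abort(sprintf("unknown variant op '%s'", op))
  )
}

VARIANT_OPS <- c("trim5_1", "trim5_2", "ext5_1", "ext5_2", "trim3_1",
                 "trim3_2", "ext3_1", "ext3_2", "nta_A", "nta_U", "sub",
                 "sub_seed", "mixed_5p", "mixed_3p")

#' Simulate an isomiR repertoire for a catalog
#'
#' For every canonical miRNA, emits the canonical sequence itself plus a
#' random draw of single-operation variants (5'/3' trims, templated
#' extensions copied from the precursor context, non-templated 3' additions,
#' internal substitutions, mixed variants). The generating operation's variant
#' class and seed-change status are recorded as ground truth; sequences are
#' unique within each parent.
#'
#' @param catalog Output of [simulate_catalog()].
#' @param config A [simulation_config()].
#' @return Tibble: `isomir_id`, `parent`, `sequence`, `variant_op`,
#'   `true_class`, `true_seed_changing`.
#' @export
simulate_repertoire <- function(catalog, config = simulation_config()) {
  config <- as_sim_config(config)
  if (nrow(catalog) == 0) abort("catalog is empty.")
  withr::with_seed(child_seed(config$rng_seed, 2L), {
    rng <- config$isomirs_per_mirna
    purrr::pmap_dfr(catalog, function(mirna_id, mature_seq, flank5, flank3) {
      n_iso <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
      rows <- list(tibble(
        isomir_id = paste0(mirna_id, ".ref"), parent = mirna_id,
        sequence = mature_seq, variant_op = "canonical",
        true_class = "canonical", true_seed_changing = FALSE
      ))
      ops <- sample(VARIANT_OPS, min(n_iso - 1L, length(VARIANT_OPS)))
      for (op in ops) {
        v <- apply_variant_op(op, mature_seq, flank5, flank3)
        rows[[length(rows) + 1L]] <- tibble(
          isomir_id = paste0(mirna_id, ".", op), parent = mirna_id,
          sequence = v$seq, variant_op = op, true_class = v$class,
          true_seed_changing = v$seed
        )
      }
      out <- bind_rows(rows)
      out[!duplicated(out$sequence), ]
    })
  })
}

#' Simulate a cohort metadata table
#'
#' Scores are integer risk percentiles (0-99) spanning both sides of the 75th
#' percentile cutoff; hemolysis Cts are drawn so that delta-Ct
#' (Ct miR-23a-3p minus Ct miR-451a) is below 7 except for `n_hemolytic`
#' requested failures. A spike-in recovery Ct is carried as pass-through
#' metadata.
#'
#' @param config A [simulation_config()].
#' @return Tibble: `sample_id`, `score`, `ct_mir23a`, `ct_mir451a`,
#'   `spike_in_ct`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  config <- as_sim_config(config)
  withr::with_seed(child_seed(config$rng_seed, 3L), {
    n <- config$n_samples
    n_high <- min(max(1L, round(n * config$high_frac)), n - 1L)
    scores <- sample(c(sample(75:99, n_high, replace = TRUE),
                       sample(0:66, n - n_high, replace = TRUE)))
    ct451 <- round(rnorm(n, 19, 0.8), 2)
    delta <- runif(n, 3.5, 6.5)
    if (config$n_hemolytic > 0) {
      delta[sample(n, config$n_hemolytic)] <- runif(config$n_hemolytic, 7.5, 9)
    }
    tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      score = as.integer(scores),
      ct_mir23a = round(ct451 + delta, 2),
      ct_mir451a = ct451,
      spike_in_ct = round(rnorm(n, 21, 0.4), 2)
    )
  })
}

# Gaussian-copula link: population Spearman rho_s between a feature's latent
# abundance and the score ranks is hit by using latent Pearson
# rho_n = 2 sin(pi rho_s / 6) on normal scores.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

planted_latent <- function(z, rho_s) {
  rho_n <- spearman_to_pearson(rho_s)
  rho_n * z + sqrt(1 - rho_n^2) * rnorm(length(z))
}

#' Simulate an isomiR count matrix with planted associations
#'
#' Every feature's per-sample relative abundance is a log-normal perturbation
#' of a feature baseline (Poisson-log-normal counts, i.e. overdispersed).
#' Planted features replace the independent log-normal noise with a Gaussian
#' copula tied to the score's normal ranks, so their population Spearman
#' correlation with the score equals the target. Three plantings exist:
#' miRNA-level signals (a dominant lead isomiR at `effect_rho` plus coherent
#' weaker siblings, so the aggregated parent also correlates), the
#' isomiR-only scenario (one seed-changing isomiR planted positive with a
#' compensating sibling holding the aggregated parent flat) and plain null
#' features. Optionally one library is degraded into an outlier by zeroing
#' `outlier_zero_frac` of the features detected in every library.
#'
#' @param repertoire Output of [simulate_repertoire()].
#' @param cohort Output of [simulate_cohort()].
#' @param config A [simulation_config()].
#' @return List with `counts` (tibble: `feature_id`, `parent`, one integer
#'   column per sample) and `truth` (list: `planted` tibble with
#'   `feature_id`, `level`, `parent`, `scenario`, `sign`, `target_rho`;
#'   `outlier_library_id`; `seed_changing_ids`).
#' @export
simulate_counts <- function(repertoire, cohort, config = simulation_config()) {
  config <- as_sim_config(config)
  if (nrow(repertoire) == 0 || nrow(cohort) == 0) {
    abort("repertoire and cohort must be non-empty.")
  }
  withr::with_seed(child_seed(config$rng_seed, 4L), {
    n <- nrow(cohort)
    z <- qnorm((rank(cohort$score, ties.method = "average") - 0.5) / n)
    disp <- config$dispersion
    parents <- unique(repertoire$parent)
    M <- length(parents)

    # pick scenario parents by eligibility, then assign parent weights
    n_per_parent <- table(repertoire$parent)[parents]
    has_seed_var <- vapply(parents, function(p) {
      any(repertoire$parent == p & repertoire$true_seed_changing &
            repertoire$variant_op != "canonical")
    }, logical(1))
    elig_io <- parents[n_per_parent >= 3 & has_seed_var]
    if (length(elig_io) < config$n_planted_isomir_only) {
      abort("not enough parents with a seed-changing variant for the isomiR-only scenario.")
    }
    io_parents <- if (config$n_planted_isomir_only > 0) {
      sample(elig_io, config$n_planted_isomir_only)
    } else character(0)
    elig_ms <- setdiff(parents, io_parents)
    if (length(elig_ms) < config$n_planted_mirna) {
      abort("not enough parents for the requested miRNA-level plantings.")
    }
    ms_parents <- if (config$n_planted_mirna > 0) {
      sample(elig_ms, config$n_planted_mirna)
    } else character(0)

    w <- exp(rnorm(M, 0, 0.9))
    names(w) <- parents
    # planted parents are made comfortably abundant so they clear the
    # abundance filter by construction
    w[c(io_parents, ms_parents)] <- quantile(w, 0.6)

    feats <- repertoire$isomir_id
    F <- length(feats)
    expected <- matrix(0, F, n, dimnames = list(feats, cohort$sample_id))
    planted <- list()

    for (p in parents) {
      idx <- which(repertoire$parent == p)
      k <- length(idx)
      ids <- repertoire$isomir_id[idx]
      canon <- which(repertoire$variant_op[idx] == "canonical")[1]
      base <- exp(rnorm(k, 0, 0.8))
      base[canon] <- base[canon] * 3          # canonical usually dominates
      base <- base / sum(base)

      if (p %in% ms_parents) {
        lead <- canon
        share <- rep((1 - config$lead_share) / max(k - 1, 1), k)
        share[lead] <- if (k > 1) config$lead_share else 1
        lat <- matrix(0, k, n)
        for (j in seq_len(k)) {
          rho_t <- if (j == lead) config$effect_rho else
            config$effect_rho * config$sib_coupling
          lat[j, ] <- planted_latent(z, rho_t)
        }
        expected[idx, ] <- w[p] * share * exp(disp * lat - disp^2 / 2)
        planted[[length(planted) + 1L]] <- bind_rows(
          tibble(feature_id = p, level = "mirna", parent = p,
                 scenario = "mirna_signal", sign = 1,
                 target_rho = config$effect_rho),
          tibble(feature_id = ids[lead], level = "isomir", parent = p,
                 scenario = "lead", sign = 1, target_rho = config$effect_rho),
          tibble(feature_id = ids[-lead], level = "isomir", parent = p,
                 scenario = "sib", sign = 1,
                 target_rho = config$effect_rho * config$sib_coupling)
        )
      } else if (p %in% io_parents) {
        # the planted seed-changing isomiR tracks the score; the canonical
        # sequence compensates (second pass below) so the parent's share of
        # the library stays exactly constant: total miRNA expression is
        # stable while its isoform composition shifts with the score
        iso_j <- which(repertoire$true_seed_changing[idx] &
                         repertoire$variant_op[idx] != "canonical")[1]
        comp_j <- canon
        others <- setdiff(seq_len(k), c(iso_j, comp_j))
        lat <- planted_latent(z, config$effect_rho)
        s1 <- pmin(0.12 * exp(disp * lat - disp^2 / 2), 0.6)
        expected[idx[iso_j], ] <- w[p] * s1
        expected[idx[comp_j], ] <- 0           # filled in the second pass
        if (length(others) > 0) {
          ob <- base[others] / sum(base[others]) * 0.28
          eps <- matrix(rnorm(length(others) * n), length(others), n)
          expected[idx[others], ] <- w[p] * ob * exp(disp * eps - disp^2 / 2)
        }
        planted[[length(planted) + 1L]] <- bind_rows(
          tibble(feature_id = ids[iso_j], level = "isomir", parent = p,
                 scenario = "isomir_only", sign = 1,
                 target_rho = config$effect_rho),
          tibble(feature_id = ids[comp_j], level = "isomir", parent = p,
                 scenario = "compensator", sign = -1,
                 target_rho = NA_real_)
        )
      } else {
        eps <- matrix(rnorm(k * n), k, n)
        expected[idx, ] <- w[p] * base * exp(disp * eps - disp^2 / 2)
      }
    }

    # second pass: for each isomiR-only parent, size the compensating
    # canonical so the parent's relative library share kappa is identical in
    # every sample; after column normalisation the aggregated parent is then
    # flat up to Poisson noise
    for (p in io_parents) {
      idx <- which(repertoire$parent == p)
      comp_row <- idx[which(repertoire$variant_op[idx] == "canonical")[1]]
      p_other <- colSums(expected[idx, , drop = FALSE])   # comp row is 0
      rest <- colSums(expected) - p_other
      kappa <- min(1.3 * max(p_other / (p_other + rest)), 0.5)
      expected[comp_row, ] <- (kappa * rest - (1 - kappa) * p_other) / (1 - kappa)
    }

    prop <- sweep(expected, 2, colSums(expected), "/")
    depth <- runif(n, config$depth_range[1], config$depth_range[2])
    counts <- matrix(rpois(F * n, t(t(prop) * depth)), F, n,
                     dimnames = dimnames(prop))
    mode(counts) <- "integer"

    outlier_id <- NA_character_
    if (config$outlier_library) {
      low_ids <- cohort$sample_id[cohort$score < 75]
      if (length(low_ids) == 0) low_ids <- cohort$sample_id
      outlier_id <- sample(low_ids, 1)
      common <- rowSums(counts > 0) == n
      kill <- sample(which(common),
                     floor(sum(common) * config$outlier_zero_frac))
      counts[kill, outlier_id] <- 0L
    }

    planted_tbl <- if (length(planted) > 0) bind_rows(planted) else
      tibble(feature_id = character(), level = character(),
             parent = character(), scenario = character(),
             sign = numeric(), target_rho = numeric())
    counts_tbl <- bind_cols(
      tibble(feature_id = feats, parent = repertoire$parent),
      as_tibble(counts)
    )
    list(
      counts = counts_tbl,
      truth = list(
        planted = planted_tbl,
        outlier_library_id = outlier_id,
        seed_changing_ids =
          repertoire$isomir_id[repertoire$true_seed_changing]
      )
    )
  })
}

#' Simulate a cholesterol-efflux plate
#'
#' Per sample, three medium/lysate CPM pairs plus one shared blank pair.
#' Specific efflux is planted to correlate with the score at `efflux_r`
#' (Pearson, population). A fraction of samples receive one aberrant replicate
#' offset by `aberrant_shift` percent of total efflux, guaranteed to trip the
#' 1.15-SD triplicate rule (the two clean replicates are kept within 5% of the
#' offset of each other).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config A [simulation_config()].
#' @return List with `plate` (tibble: `sample_id`, `replicate`, `cpm_medium`,
#'   `cpm_lysate`, `is_blank`) and `aberrant_samples` (character).
#' @export
simulate_efflux <- function(cohort, config = simulation_config()) {
  config <- as_sim_config(config)
  if (nrow(cohort) == 0) abort("cohort is empty.")
  withr::with_seed(child_seed(config$rng_seed, 5L), {
    n <- nrow(cohort)
    sscore <- as.numeric(scale(cohort$score))
    specific <- config$efflux_mean + config$efflux_sd *
      (config$efflux_r * sscore + sqrt(1 - config$efflux_r^2) * rnorm(n))
    total <- pmax(specific + config$blank_efflux, 0.5)

    n_ab <- round(config$aberrant_frac * n)
    ab_samples <- if (n_ab > 0) sample(cohort$sample_id, n_ab) else character(0)

    rows <- purrr::map_dfr(seq_len(n), function(i) {
      tot_rep <- total[i] + rnorm(3, 0, config$replicate_sd)
      if (cohort$sample_id[i] %in% ab_samples) {
        shift <- sample(c(-1, 1), 1) * config$aberrant_shift
        tot_rep[2] <- tot_rep[1] + runif(1, -0.05, 0.05) * abs(shift)
        tot_rep[3] <- mean(tot_rep[1:2]) + shift
      }
      tot_rep <- pmin(pmax(tot_rep, 0.2), 99)
      lys <- config_lysate_cpm() * exp(rnorm(3, 0, 0.1))
      tibble(
        sample_id = cohort$sample_id[i], replicate_index = 1:3,
        cpm_medium = round(tot_rep / (100 - tot_rep) * lys, 1),
        cpm_lysate = round(lys, 1), is_blank = FALSE
      )
    })
    blank_tot <- config$blank_efflux + rnorm(1, 0, config$replicate_sd)
    lys_b <- config_lysate_cpm() * exp(rnorm(1, 0, 0.1))
    blank <- tibble(
      sample_id = "BLANK", replicate_index = 1L,
      cpm_medium = round(blank_tot / (100 - blank_tot) * lys_b, 1),
      cpm_lysate = round(lys_b, 1), is_blank = TRUE
    )
    list(plate = bind_rows(rows, blank), aberrant_samples = ab_samples)
  })
}

config_lysate_cpm <- function() 4e4

#' Simulate a full synthetic dataset
#'
#' Bundles catalog, repertoire, cohort, counts (+ truth) and efflux plate.
#'
#' @param config A [simulation_config()].
#' @return List: `catalog`, `repertoire`, `cohort`, `counts`, `truth`,
#'   `efflux` (plate tibble), `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  config <- as_sim_config(config)
  catalog <- simulate_catalog(config)
  repertoire <- simulate_repertoire(catalog, config)
  cohort <- simulate_cohort(config)
  cm <- simulate_counts(repertoire, cohort, config)
  ef <- simulate_efflux(cohort, config)
  truth <- cm$truth
  truth$aberrant_samples <- ef$aberrant_samples
  list(catalog = catalog, repertoire = repertoire, cohort = cohort,
       counts = cm$counts, truth = truth, efflux = ef$plate, config = config)
}
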