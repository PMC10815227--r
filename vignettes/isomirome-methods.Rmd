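---
title: "Screening the circulating isomiR-ome: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening the circulating isomiR-ome: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirome)
```

This vignette is the package's account of its science: the screen it
implements, the assumptions behind each stage, what the synthetic cohort
does and does not emulate, the numerical choices, and the design decisions
made where the design was genuinely open. It states no empirical result
that the package's tests do not themselves compute.

## 1. The screen

The object of study is the *circulating isomiR-ome*: every unique small-RNA
sequence assigned to a mature miRNA in plasma sequencing libraries. A
sequence is either the canonical mature form (the database sequence) or an
isomiR — a variant trimmed or extended at the 5′ or 3′ end (from imprecise
Drosha/Dicer cleavage, exonuclease nibbling, or non-templated nucleotide
addition), carrying internal substitutions, or both. Because nucleotides
2–7 (the seed) dominate target recognition, any 5′ shift or seed-window
substitution redirects the variant to a different target repertoire, so an
isomiR can track a phenotype its parent miRNA does not.

Given an isomiR × library raw count table, a continuous clinical score per
library (a 0–99 risk percentile), and hemolysis qPCR values, the pipeline
runs:

hemolysis gate → library-outlier removal → RPM normalisation → aggregation
to miRNA level → dual abundance filter → Spearman screen with a
permutation null and BH correction → ROC-AUC discrimination → isomiR versus
parent superiority → optional cholesterol-efflux correlations.

Each stage is exported individually; `run_analysis()`/`run_pipeline()`
orchestrate them and emit a funnel report.

## 2. Quality gates

**Hemolysis.** Erythrocytes are rich in miR-451a while miR-23a-3p is a
stable plasma reference, so the difference ΔCt = Ct(miR-23a-3p) −
Ct(miR-451a) falls as red-cell contamination rises. A sample passes when
ΔCt < 7 (strict). Only the difference matters; the rule is invariant to a
common shift of both Cts.

**Library outliers.** Two signals, OR-combined: (a) the number of features
a library detects (raw count ≥ 1) among the features present in at least 5
libraries, compared against the cohort's lower Tukey fence (Q1 − 1.5 IQR);
and (b) the library's median Spearman correlation with the other libraries
on RPM values, with a 0.6 floor. The detection counts against the ≥3-library
subset are reported alongside. Two deliberate choices:

- *"Present" means raw count ≥ 1*, not an RPM floor — the simplest reading
  of a detection rate.
- *The fence carries a minimum slack of 2% of the subset size.* With
  near-complete detection the IQR collapses to zero and a bare fence would
  flag a library missing a single feature by sampling chance; a genuine
  degenerate library (the generator zeroes 70% of ubiquitous features)
  sits far below any fence, while a 0.4% shortfall is noise.

## 3. IsomiR classification

`classify_isomir()` aligns a sequence, without gaps, to the extended
canonical axis (5′ precursor flank + mature + 3′ flank when flanks are
known) and selects the placement minimising first the number of internal
substitutions, then the total end-offset magnitude, with deterministic
tie-breaking towards the canonical register (smaller |5′ offset|, then
smaller |3′ offset|, then fewer seed-window substitutions). Offsets are
bounded (5′ ∈ [−2, +4], 3′ ∈ [−4, +4], configurable); a sequence with no
admissible placement is rejected as unassignable rather than forced.

The taxonomy follows the field's standard classes: `canonical`, `iso_5p`
(pure 5′ length change), `iso_3p` (pure 3′ length change), `polymorphic`
(same ends, internal substitutions), `mixed` (anything else). Two
conventions matter:

- *Seed positions are counted on the isomiR's own 5′ end.* This is what
  makes every 5′-shifted variant seed-changing: the bases occupying
  positions 2–7 change even though the sequence content does not.
- *Substitutions are only counted where the isomiR overlaps the mature
  body.* Extension bases beyond the mature ends are compared to the
  precursor flank to call `templated` vs `non_templated` (3′ mismatch);
  with no flank available the call is `unknown`. A 3′ +A on a flank that
  continues with G is therefore a non-templated `iso_3p`, not `mixed`.

Internal insertions/deletions are out of scope — the taxonomy has no
internal-indel class, and ungapped placement keeps the classifier exact and
enumerable (the test suite checks every single-edit variant of a 50-entry
random catalog against its generating operation).

## 4. Abundance

RPM divides each library's counts by that library's total isomiR-level
count (the table's own column sum, computed before any filtering) × 10⁶.
miRNA-level counts are the per-parent sums of raw isomiR counts; totals are
conserved exactly, and because both levels share the library denominator,
aggregating raw counts then normalising equals summing isomiR RPMs.

The dual abundance filter keeps features with mean RPM > 5 **and** max
RPM > 50 (strict inequalities), applied identically at both levels. The
dynamic range is max/min RPM; a zero minimum leaves it undefined (`NA`)
rather than infinite — and an undefined range never wins a superiority
comparison.

## 5. The correlation screen

**Spearman ρ** is the Pearson correlation of mid-ranks (ties averaged);
constant profiles have no defined rank correlation and are excluded with a
logged reason, not silently dropped.

**Permutation null.** The score assignment is shuffled `n_perm` times
(default 10,000; desk-scale tests use 2,000) and
p = #{|ρ_perm| ≥ |ρ_obs|}/n_perm. Three choices:

- *"Better correlation" means larger absolute ρ.* Negative correlations are
  real discoveries (the screen keeps candidates at ρ ≤ −0.55), so a signed
  rule would be inconsistent with the candidate definition.
- *One shared shuffle stream for all features.* This preserves the
  cross-feature dependence of the null, makes the whole screen
  O(n_perm × features) by a single rank-matrix product, and renders results
  jointly reproducible from one seed.
- *The plain count/n_perm estimator* (zero p-values possible) is the
  default; `add_one = TRUE` gives the (count+1)/(n_perm+1) variant for
  users who need strictly positive p-values.

**Multiple testing: the family question.** The screen-then-correct
ordering — gate candidates at |ρ| ≥ 0.55, permutation-test only them, then
BH — is the literal procedure and the package default
(`p_family = "candidates"`). It has a property users must understand:
conditioning on candidacy truncates null p-values to roughly
(0, P(|ρ| ≥ 0.55)) ≈ (0, 0.064) at n = 12, so BH over candidates passes
almost every candidate — the FDR among discoveries is not controlled at the
nominal level. This is not an implementation artifact; it is what makes a
12-sample screen report dozens of isomiR hits. The alternative
(`p_family = "filtered"`) computes permutation p-values for *every*
abundance-filtered feature and adjusts over that family, restoring
selection-free FDR control at a real cost in power: with ~400 filtered
features at n = 12, only features with empirical |ρ| ≳ 0.88 survive. The
package exposes both; the acceptance suite verifies type-I control and
planted-signal recovery under `"filtered"`, and the small-cohort headline
structure under the default. In either mode `significant` requires
candidacy *and* p-adj < α.

**ROC.** AUC is the Mann–Whitney statistic with ties counted ½, oriented
"higher abundance predicts high risk" with no automatic flip (an AUC below
0.5 is reported as such; `flip_negative` reverses orientation for
negative-ρ features and records the flip). The 95% CI uses DeLong's
placement-variance estimator, truncated to [0, 1]; *discriminative* means
the lower bound exceeds 0.5. DeLong was chosen because the original report
names no CI method and DeLong is the field default that needs no
resampling; at 6 vs 6 the normal approximation is crude, which is one
reason discrimination is a flag, not a ranking.

**Superiority.** For each candidate isomiR, four strict comparisons against
its parent's record on the identical cohort: |ρ| larger, p-adj smaller
(a parent that never entered the correction family counts as p-adj = 1),
dynamic range larger (undefined never wins), AUC larger. `superior`
requires all four; `isomir_only` means significant isomiR with
non-significant parent — with a seed change, the headline finding class.

## 6. The synthetic cohort

The generator emulates the shape of a small plasma pilot: 13 libraries,
roughly 6 above and 7 below the 75th risk percentile (integer scores, ties
allowed), hemolysis ΔCt drawn in the passing range unless failures are
requested, one degenerate library, library depths 1–3 million reads, 80
canonical miRNAs with 3–8 isomiRs each.

**Count model.** Counts are Poisson–log-normal: each feature's per-sample
relative abundance is its baseline times exp(σ·ε) with σ = 0.7, columns are
normalised to proportions, scaled by a uniform random depth and Poisson
sampled. A gamma-mixed Poisson was the obvious alternative; the log-normal
latent was chosen because planted associations use a Gaussian copula — the
latent Pearson correlation 2·sin(πρ_s/6) yields a population *Spearman* of
exactly ρ_s between abundance and score, which a gamma mixture cannot
guarantee in closed form. Normal scores of the score's mid-ranks make the
planted target well-defined under ties.

**Planted structure.**

- *Whole-miRNA signals* (2 by default): every isomiR of the parent tracks
  the score at the target ρ (default 0.9) with independent residual noise —
  co-produced variants of one transcript move together — so the aggregated
  parent is at least as correlated as any single isomiR.
- *The isomiR-only scenario* (1 by default): one seed-changing variant
  tracks the score while the canonical sequence is sized, sample by sample,
  so the parent's *relative library share is identical in every sample*.
  Total miRNA expression stays flat while isoform composition shifts with
  the score; the aggregated parent is an exact null on the RPM scale (its
  empirical rank correlation is pure Poisson-jitter noise — Spearman is
  magnitude-blind). An earlier design compensating absolute mass left the
  parent carrying sibling noise plus a systematic RPM-denominator
  component, which at n = 12 could make it spuriously significant.
- *Null features*: independent log-normal noise around their baselines.

Two generator-realism constraints were found to matter at desk scale and
are worth knowing about. First, the RPM denominator must be
composition-stable: with few miRNAs and highly skewed, noisy weights, the
library total itself fluctuates enough to act as a common-mode factor on
every feature's rank profile (real tables with ~10³ features do not do
this); hence 80 parents with weight sd(log) = 0.9. Second, planted features
are made comfortably abundant so the abundance filter never interacts with
recovery tests. At this scale the abundance filter does little work —
unlike the real funnel, where it removes >99% of isomiRs — so a green
headline test establishes the screen's logic, not its behaviour on a
404,000-row table.

**Efflux plate.** Per sample, three medium/lysate CPM pairs plus one
no-plasma blank. Specific efflux is drawn at a population Pearson
correlation of −0.577 with the score (mean 12%, sd 3%, blank 3%, replicate
sd 0.25%). A fraction 5/13 of samples get one aberrant replicate offset by
6 percentage points, with the two clean replicates kept within 5% of that
offset of each other — which guarantees the 1.15-SD rule removes exactly
the aberrant value (the largest possible deviation of one value in a
triplicate is 2/√3 ≈ 1.1547 SD, so detectability requires the clean pair to
be tight).

**What a green test does not establish.** The generator plants monotone,
single-factor associations with log-normal noise; it does not emulate
real library-preparation batch effects, cross-mapping between paralogous
miRNAs, adapter artifacts, compositional shifts from a few dominant
erythrocyte miRNAs, or the empirical abundance spectrum of plasma. Recovery
of planted signals shows the statistics are wired correctly, not that the
screen would rank the same biology in a real cohort.

## 7. Efflux arithmetic

Total efflux = 100 × medium/(medium + lysate) — scale-invariant in the
plating density. Specific efflux subtracts the blank's total efflux and may
be slightly negative (reported as-is, flagged low). Triplicate cleaning is
a single pass on the *derived per-replicate efflux percentages* (not raw
CPM): values at least 1.15 sample SDs (n−1 denominator) from the triplicate
mean are removed, without re-iteration; if fewer than two values would
remain, all are kept and the sample flagged. Cleaning the percentage rather
than the CPM makes a single bad well detectable regardless of plating
density; both alternatives are a flag away in `summarize_efflux()`.
Correlations of specific efflux with the score and with feature RPMs are
Pearson with the usual two-sided test — the screen reserves rank
correlation for abundance-score associations.

## 8. Numerical and degenerate-case choices

- Rank computations use mid-ranks throughout; permutation comparisons use
  |ρ_perm| ≥ |ρ_obs| − 10⁻¹² to keep the identity permutation counted
  under floating-point noise.
- BH is `stats::p.adjust(method = "BH")`; the test suite checks it and the
  Spearman and AUC implementations against independent brute-force
  implementations (hand step-up, mid-rank Pearson from the definition,
  all-pairs concordance counting).
- A zero-total library is a hard error naming the library; a constant
  feature is excluded with a reason; a single-class cohort skips ROC with a
  note instead of failing the run.
- All randomness flows from one integer seed per run; derived seeds stay
  within 32-bit range.
- Desk-scale tests shuffle 2,000 times instead of 10,000 to stay within CI
  budgets; the pipeline default remains 10,000.

## 9. Known limitations

- At n = 12 the sampling noise of an empirical rank correlation is ~0.3 for
  a null feature and ~0.07 even for ρ = 0.9, so any single feature's fate
  in one cohort is substantially stochastic; the screen's guarantees are
  distributional.
- Candidates-only BH does not control FDR under selection (section 5); the
  corrected family trades most of the small-n power away. Neither mode
  makes a 12-sample pilot confirmatory.
- DeLong CIs at 6v6 are approximate; discrimination calls near the 0.5
  boundary should not be over-read.
- The classifier trusts the count table's parent assignment and does not
  attempt cross-mapping resolution, A-to-I editing inference or
  arm-switching analysis.
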