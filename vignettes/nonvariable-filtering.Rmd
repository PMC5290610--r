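---
title: "Non-variable CpG filtering for methylation EWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-variable CpG filtering for methylation EWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Epigenome-wide association studies (EWAS) on Illumina 450K/EPIC arrays test
hundreds of thousands of CpGs, yet in any one tissue a large share of those
CpGs barely varies between individuals: they sit fully methylated or fully
unmethylated in essentially every sample. Testing them anyway inflates the
multiple-testing burden and costs power at the CpGs that do carry signal.

`cpgnonvar` implements an empirically driven data-reduction method: build a
tissue-specific list of non-variable CpGs from independent cohorts, and
apply it to a new study with a *confirm-and-remove* rule — remove a CpG only
when the reference list calls it non-variable **and** the new data confirm
that, then re-run the multiple-test correction on the reduced set. This is
deliberately more conservative than filtering on within-study variability
alone (which biases toward significant results) and more powerful than not
filtering at all.

# The variability statistic

For each CpG with beta values $x_1, \dots, x_n$ across samples, the
**reference range** is

$$\mathrm{RR} = q_{0.90} - q_{0.10},$$

the spread between the 90th and 10th percentile. A CpG is called
**non-variable** in a tissue when $\mathrm{RR} < 0.05$, i.e. the central 80%
of the population spans less than 5% of the beta scale. The trimmed range is
robust to a few outlying samples while still measuring population-level
variability; the 5% threshold asks only that the population as a whole
varies, deliberately stricter than the 1% effect sizes sometimes tested
between groups.

**Quantile estimator.** List membership near the threshold depends on how
percentiles are interpolated, so the estimator is fixed and pinned by an
oracle test: with sorted values $x_{(1)} \le \dots \le x_{(n)}$ and level
$p$, let $h = (n-1)p + 1$; then
$q_p = x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)\,
(x_{(\lfloor h \rfloor + 1)} - x_{(\lfloor h \rfloor)})$ — the common
linear-interpolation default. `reference_range()` computes this formula
directly on row-sorted matrices; the tests cross-check it against
`stats::quantile(type = 7)` as an independent route.

**Boundary.** Calling uses a strict `<` at the threshold ("less than 5%");
an inclusive variant is available via `cpg_params(nonvar_inclusive = TRUE)`
because published descriptions of such rules are frequently ambiguous at
equality, and reproducing someone else's list may require the other reading.

# Quality control

Bead-count filters run before anything else, in the order probe filter →
sample filter → correlation screen, each stage logged in the `qc_report`:

* a **CpG** is removed when *strictly more than* 5% of samples measured it
  with fewer than 3 beads;
* a **sample** is removed when the fraction of its CpGs with fewer than 3
  beads *reaches* 2.5%. The inclusive boundary here is a documented
  decision — "if 2.5% … had fewer" reads as reaching the stated fraction —
  and both boundaries are parameterised (`sample_fail_inclusive`) so either
  reading is reproducible.

The correlation screen scores each sample by its mean Pearson correlation to
all other samples (Spearman available). Visual inspection of correlation
heat maps does not reproduce, so two logged, automated policies replace it:
`robust_z(k)` flags scores below median − k·MAD (default, k = 3) and
`absolute_floor(c0)` flags scores below a fixed value. Whole studies can be
flagged when more than half their samples are flagged
(`flag_outlier_studies()`), the automated analogue of dropping an entire
incoherent study from a meta-analysis. Zero-variance samples have undefined
correlations; they are flagged explicitly, never silently scored 0.

# Comparing lists

`intersect_lists()` works on the **common universe** — the intersection of
the lists' tested CpG sets — because cohorts assembled from different
studies end up with different complete-case universes, and an overlap is
only meaningful where all lists could have called a CpG.

`overlap_permutation_test()` asks whether the k-way overlap exceeds chance:
each permutation draws, from *each list's own universe*, a uniform random
subset of that list's size, and the statistic is the intersection size on
the common universe. This matches how the observed overlap is constrained.
The empirical p-value uses the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\}) / (1 + N)$, so $p = 0$ is never
reported and resolving $p < 10^{-4}$ requires $N \ge 10{,}000$ — the
default.

`list_concordance()` reports overlap fraction
$|a \cap b| / \min(|a|, |b|)$ (the robustness metric for lists built under
different processing strategies) alongside Jaccard.

# Genomic-feature enrichment

`enrichment_permutation()` compares a list's counts per gene feature
(promoter, intragenic, 3′, intergenic) and CpG-island feature (island,
shores, shelves, none) to random lists of the same size drawn from the
**tested background** — the tissue's own universe, never the full array,
since array content differs from what survives cohort assembly. Fold change
is observed over mean permuted count; a feature whose permutation mean is 0
gets an undefined (NA) fold change with a warning rather than an infinity.

The default p-value is two-sided (twice the smaller add-one tail, capped at
1) because both enrichment and depletion are of interest; one-sided options
are exposed. BH adjustment runs jointly across the 9 features of both
families by default (`families = "joint"`), matching how the two families
are usually presented together; `families = "separate"` adjusts per family.
All multiple-testing goes through `bh_fdr()`, a validating wrapper around
the standard step-up.

# The EWAS model

`fit_linear_ewas()` fits, per CpG, ordinary least squares of methylation on
a two-level exposure plus optional numeric covariates, vectorised across all
CpGs. The response is the **beta value** by default; betas are
heteroscedastic near the scale boundaries, and an M-value response is
available (`response = "m"`) — but the **delta beta** effect size is always
the raw difference of group mean betas, regardless of covariates or
modelling scale, because effect sizes are interpreted on the beta scale.

Numerical choices worth knowing:

* Degenerate fits with zero residual variance return $p = 1$, never NaN, so
  a numerically constant CpG can never become a spurious hit.
* Per-CpG statistics are computed with row-independent arithmetic
  (element-wise products and `rowSums`), so a CpG's raw statistic is
  bit-identical whether it is fit inside the full matrix or a filtered
  subset. This makes the central invariant of the filter — *filtering
  changes only the multiple-testing family, never the raw p-values* —
  exactly testable.

`hit_calling()` gates on both FDR < 0.05 and |Δβ| ≥ 0.1: a statistical and
a biological threshold, jointly.

# Confirm-and-remove and the power experiment

`confirm_and_filter()` removes exactly the intersection of (a) the reference
list and (b) the CpGs non-variable within the study itself, so
$|\text{retained}| = |\text{tested}| - |\text{study-nonvariable} \cap
\text{reference}|$ holds identically. CpGs the reference calls non-variable
but that vary in the new data are kept.

`subsample_experiment()` emulates a low-powered study: 10 replicates each
draw 12 + 12 samples per group without replacement, run the EWAS unfiltered
and filtered, and report adjusted p at tracked CpGs plus hit counts per arm.
Study reference ranges are **recomputed within each replicate** by default —
confirmation should use the data actually analysed — with
`recompute_ranges = FALSE` available to confirm against full-cohort ranges.
A single master seed derives per-replicate seeds deterministically, so runs
are reproducible end to end.

# What the simulator emulates — and what it does not

`simulate_beta_matrix()` generates the features the pipeline's behaviour
depends on:

* **bimodal non-variable CpGs** at planted means above 0.80 or below 0.16
  (10% + 10% of CpGs by default), with truncated-Gaussian noise
  (`noise_sd = 0.005`);
* **variable null CpGs** with per-CpG spread SD in \[0.07, 0.15\], so the
  10–90 range clears 0.15;
* **planted signals** (0.1% of CpGs, 50 in the default 50,000) shifting the
  exposed group by Δβ = 0.10 — the magnitude at which variability filtering
  is expected to pay off;
* cohorts of 60 samples (30 exposed / 30 control), large enough that ten
  12 + 12 sub-samples are genuinely distinct draws.

Truncated-Gaussian noise was chosen over Beta-distributed noise because the
object under test is order statistics of the values, not methylome realism;
the truncation keeps everything in \[0, 1\]. `simulate_bead_counts()` plants
failing probes/samples at rates that clear the QC rules;
`simulate_annotation()` can bias island/promoter probabilities for a
designated subset (renormalised), giving a known expected enrichment.

The simulator does **not** model Infinium I/II probe chemistry, batch
effects, cell-composition mixtures, or spatially correlated CpGs. Passing
tests therefore demonstrate that the statistics, thresholds and permutation
machinery behave exactly as specified on data with known truth — not that
any particular biological cohort will show a given list size or enrichment.
Normalisation (e.g. BMIQ) and cell-composition correction are upstream of
this package: every function accepts already-processed betas unchanged.

# Problem sizes and runtime

The test suite and the acceptance script run at desk scale by design:
50,000 CpGs × 24–60 samples for parameter-recovery and power runs, 1,000
random CpGs per oracle sweep, 5,000–10,000 permutations where a Monte-Carlo
standard error bound is asserted, and exhaustive enumeration on a 12-CpG
universe where the hypergeometric oracle is exact. These sizes give tight
statistical checks in minutes on one core; all of them scale up linearly if
larger runs are wanted.

# Known limitations

* The per-CpG model is ordinary least squares; moderated (limma-style)
  variance shrinkage and robust alternatives are out of scope.
* The correlation screen's default `robust_z(3)` is a reasonable automated
  stand-in for visual inspection, but any automated rule will differ from a
  human call on borderline studies; the policy and thresholds are logged so
  the choice is auditable.
* Whether to treat gene and island features as one or two BH families is a
  presentation choice; both are supported, and the default (joint) is the
  more conservative within-call correction.
* The tissue lists this package builds are only as good as the cohorts they
  are built from: variability due to technical factors is deliberately left
  in (no cross-study normalisation), making lists conservative but robust
  to study-specific processing.
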