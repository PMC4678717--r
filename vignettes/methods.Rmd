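---
title: "Methods: cross-validated QMDR epistasis discovery for quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-validated QMDR epistasis discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epiqmdr)
```

## The problem and the model

Single-locus association scans miss joint genotype effects that deviate
from the sum of single-locus effects (statistical epistasis). This
package implements a complete discovery pipeline for pairwise epistasis
on a quantitative trait: quality control, covariate residualization,
candidate filtering, an exhaustive cross-validated QMDR search, pooled
permutation significance, an explicit test of non-additivity and a
variance-explained comparison.

The working model for the trait is

y = β₀ + covariates·β + Σⱼ βⱼ gⱼ + Σ_(pairs) M[g₁, g₂] + ε,
ε ~ N(0, σ²),

where gⱼ ∈ {0,1,2} counts minor alleles and M is a 3×3 cell-mean
matrix. The synthetic-data generator draws from exactly this model; the
analysis stages assume nothing beyond it except exchangeability under
the permutation nulls.

## Quality control

Filters run in a fixed order: sample call rate (≥ 0.90), SNP call rate
(≥ 0.95), exact Hardy–Weinberg test (p ≥ 1e-7), MAF (≥ 0.05), LD
pruning (r² < 0.6) and π̂ relatedness (≤ 0.3). Defaults mirror standard
cohort practice for gene-centric arrays. Decisions the literature
leaves open, fixed here deterministically:

* **LD pruning tie-break** — within each chromosome in map order, the
  *later* SNP of an offending pair is removed (PLINK-like greedy scan
  against already-kept SNPs).
* **Relatedness tie-break** — the pair member with the lower call rate
  is removed; ties by sample-ID order.
* **π̂ estimator** — method-of-moments from IBS counts given allele
  frequencies, component estimates clamped to [0, 1] and renormalized.
  It is biased slightly upward for unrelated pairs (clamping at zero)
  and needs a few hundred informative SNPs before the 0.3 threshold
  separates cleanly; pairs sharing fewer than `pihat_min_snps` (default
  50) informative SNPs are skipped.
* **HWE exact test** — plain (not mid-p) conditional test via the
  stable recurrence. Tables whose conditional probability is within
  relative 1e-9 of the observed probability count as "as extreme", so
  mathematically tied tables are pooled identically regardless of
  floating-point evaluation order.
* **Missing calls** — excluded pairwise from every statistic; no
  imputation.

Note that the QC sequence is *statistically* idempotent only away from
the thresholds: removing related individuals changes downstream sample
MAF estimates, so a cohort dense with borderline-MAF SNPs can cascade
on re-application. The idempotence test uses data away from thresholds.

## Covariate residualization and candidate filtering

The trait is residualized by OLS on an intercept, the covariates (age,
age², sex, ancestry PCs, cohort indicators if supplied) and optionally
an additive index SNP; residuals feed every later stage. The
main-effect screen regresses the residual trait on each SNP (intercept
+ additive code; two-sided p from t with n−2 df) and retains SNPs with
p strictly below the cutoff (default 0.016). The cutoff is a config
value — the original choice was made by visual inspection of the
p-value distribution, which is not automated here.

The knowledge filter operates on a user-supplied gene–gene table (one
row per gene-per-source support) rather than bundled databases, which
are external and version-dependent. The implication index of a gene
pair is the sum of the two genes' source counts; each source counts
once per gene, the per-gene-sum reading of the printed definition
(whether a source shared by both genes should count once per *pair* is
not decidable from the definition alone). Pairs with index ≥ 5
(default) are expanded to SNP pairs by Cartesian product over a SNP→
gene map, deduplicated, self-pairs dropped. In `filter_mode = "both"`
the pipeline searches the *union* of the two candidate-pair sets; the
original analyses ran the filters as parallel arms, and union is the
conservative superset of either arm.

## The QMDR engine

Per fold (10 folds; seeded shuffle + round-robin, sizes differing by at
most one): cells are labelled on the training nine-tenths with the
*training* overall mean (the "within the dataset" phrasing in the MDR
literature is ambiguous; training-only avoids test-set leakage),
strictly-greater means high. The statistic is the pooled-variance
Student t (the MDR-family convention; Welch is not used), signed high
minus low. Numerical guards: a pooled group with fewer than two
members, or zero pooled variance with unequal means, is an undefined
fold statistic (NA, excluded from fold means and flagged); zero pooled
variance with equal means is t = 0.

Held-out members of cells that were empty in training join the **low**
pool at testing time (`empty_cell_policy = "low"`, configurable to
`"drop"`): deterministic and conservative toward the null. Ranking is
by mean testing t over defined folds (the per-fold maximum is available
via `rank_by = "max"`; the mean is the QMDR-literature convention),
ties broken by mean training t, then lexicographic pair ID — searches
are bit-reproducible. Cross-validation consistency (CVC) counts folds
in which the pair had the best training t among all evaluated pairs.
The inner loop is compiled (Rcpp): one pass accumulates per-(fold,
cell) count/sum/sum-of-squares per pair, from which all 10 training and
testing statistics follow in O(1), so a 1225-pair search at n = 1000
costs ~25 ms and the permutation null is tractable.

## Permutation significance

The trait vector is shuffled against the fixed genotype matrix (the
standard MDR permutation: it preserves genotype correlation
structure), the search re-run with the same fold plan, and the top-k
statistics pooled across permutations (defaults 1000 × 100, resolving
p near 1e-5). P-values use the add-one rule (never zero); the raw
proportion is attached alongside. Bonferroni multiplies by the number
of retained models (default top_k = 100, the multiplier that reproduces
the published corrected values). Permutations are seeded per index, so
results are independent of execution order or worker count.

A caveat the test suite makes explicit: a top-k-*selected* pooled null
is shifted upward by construction (~+0.8 at small scale); only the
unselected pool (top_k = all pairs) is centred at zero. Calibration of
the final p-values is therefore tested directly — with top_k = 1 the
nominal rejection rate at α = 0.05 with 100 permutations is exactly
5/101 by exchangeability, and the machinery is additionally checked
against a brute-force pure-R double-permutation recomputation at tiny
scale, which must agree to 1e-10.

## Explicit test of epistasis

The case/control version of the explicit test shuffles genotypes within
cases and within controls. For a quantitative trait this package
generalizes it: individuals are binned into `n_strata = 10`
trait-quantile strata and each SNP's genotype column is shuffled
independently within strata (per-stratum genotype counts preserved
exactly; strata with fewer than two members are merged downward). The
9-cell Cartesian-coded ANOVA F (categorical, up to 8 df — a single
numeric 0–8 regressor cannot represent nine cell means and is offered
only as a config mode) is recomputed per permutation and the add-one p
reported.

**Known limitation**: stratification preserves main effects only
approximately — about 4% of a main effect's variance (the
within-stratum share for 10 quantile bins of a Gaussian) leaks into the
null F. At realistic per-allele effects (~0.1 SD, the scale of the
largest common BMI loci) the test is calibrated (measured type-I 0.065
at n = 1000, 200 replicates, 99% band [0.015, 0.095]); at 0.3 SD
effects, or 0.1 SD with n ≫ 1000, it becomes anti-conservative
(measured 0.10 at n = 2000, 0.40 at β = 0.3). Interpret explicit-test
p-values for SNPs with strong main effects cautiously, or raise
`n_strata`.

## Variance comparison

Reduced model: intercept + additive index SNP + additive member SNPs.
Full model: reduced + one 9-level cell factor per interacting pair
(aliased levels dropped by `lm`). Reported: both adjusted R²
(n−1 / n−p−1 correction), the percent increase
100·(adjR²_full − adjR²_reduced)/adjR²_reduced, the chi-square LRT
n·log(RSS_r/RSS_f) on the rank difference, and the exact nested F-test.
The percent-increase ratio is meaningful only when the reduced adjusted
R² is positive; for purely epistatic members (reduced R² ≈ 0) rely on
the LRT instead.

## Synthetic data: what it does and does not emulate

Defaults describe a BMI-like adult cohort and were chosen once: age ~
U(20, 80) years, sex ~ Bernoulli(0.5), three N(0,1) ancestry PCs,
intercept 27 kg/m², age effect 0.05 and age² −5e-4 per year, sex −1,
PCs 0.5, index-SNP 0.4 per allele, residual SD 4 (so the index effect
is 0.1 SD — the scale of the largest known common-variant BMI effect).
SNPs are drawn independently under HWE (no LD; the pipeline prunes LD
anyway), missingness is uniform. `make_pure_epistasis_matrix` builds a
3×3 offset matrix with exactly zero HWE-weighted marginals (XOR pattern
double-centred under HWE weights) scaled so the HWE-weighted SD of
offsets equals `shift` — a pair carrying it has no single-SNP signal at
all, the hardest discovery case.

Not emulated: LD blocks (beyond an optional test helper), population
stratification, pedigree structure (the π̂ tests build a
parent–offspring pair by explicit gamete transmission in test code),
genotyping batch effects, non-Gaussian traits. A green end-to-end test
therefore establishes correctness of the machinery under the stated
model, not robustness to cohort pathologies.

## Reproducibility

Every stochastic entry point takes a seed; internal streams are derived
per stage/permutation index (48271-multiplier hash, kept below 2³¹) and
evaluated under a saved-and-restored RNG state, so package calls never
perturb the session RNG and identical configs give byte-identical
output files, which the acceptance suite checks with `readBin`.
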