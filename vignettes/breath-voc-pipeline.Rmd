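---
title: "Methods: from ion fragments to a cross-validated breath classifier"
author: "breathVOC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ion fragments to a cross-validated breath classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathVOC)
library(SummarizedExperiment)
```

# The analysis problem

Thermal-desorption GC-MS of exhaled breath yields, after peak detection
and retention-time alignment (xcms territory, upstream of this package),
a matrix of *ion fragments*: one row per m/z channel with a retention
time, one column per patient, entries are ion counts. A single volatile
organic compound (VOC) produces several co-eluting fragments, so the raw
matrix is strongly collinear. The scientific questions downstream are
(i) which compounds differ between patients with probable pneumonia and
clean controls, and between culture-positive and culture-negative
patients; (ii) whether those differences survive a family-level chance
assessment; and (iii) how well a multivariate classifier built on them
discriminates out of sample.

This vignette documents the modelling choices at each stage, which knobs
exist, and what the synthetic-data tests do and do not establish.

# Fragment aggregation

**Retention-time windows.** Fragments whose retention times lie within a
tolerance of each other are candidates for the same compound. The
tolerance (`halfWidth`, seconds, default 3) is applied by single-linkage
chaining after sorting by `(rt_s, fragment_id)`: a new window starts
wherever the gap between consecutive retention times exceeds the
tolerance. Chaining was chosen over fixed bins because the tolerance is a
pairwise statement; chaining is deterministic, order-independent and has
no bin-boundary artifacts. Two fragments more than the tolerance apart can
still share a window through an intermediate fragment — the intended
behaviour for a peak whose fragments straggle.

**Co-elution splitting.** Distinct compounds can leave the column at
nearly the same time, so a window may mix compounds. Within a window,
fragments of one compound are (near-)perfectly correlated across samples
— each is the compound amount times a fixed response factor — while
fragments of different compounds are not. We therefore: standardize the
fragments; take the eigendecomposition of their correlation matrix;
retain components with eigenvalue above 1 (the Kaiser rule, minimum one);
varimax-rotate the retained loadings; assign each fragment to the
component with its largest absolute loading (ties toward the lower
index); and finally prune each candidate group for coherence — while any
member's mean Pearson correlation with the rest of its group is below
`minCor` (default 0.6), the least-correlated member is split off as its
own compound.

Two of these steps deserve justification because the obvious simpler rule
fails:

* *Rotation.* When two co-eluting compounds contribute similar variance,
  the top two eigenvalues are nearly degenerate and their raw
  eigenvectors mix both compounds roughly 50/50; max-loading assignment
  on unrotated components then cannot separate them (for any two-fragment
  window the eigenvectors are exactly `(1, ±1)/√2`, so both fragments
  always prefer the first component). Varimax restores one dominant
  component per compound without changing the spanned space. Because the
  pairwise-rotation algorithm can stall in a symmetric local optimum when
  started from the identity, the rotation is restarted from a small fixed
  set of deterministic orthogonal matrices and the best varimax objective
  is kept.
* *Coherence pruning.* Summation is only justified for strongly
  correlated fragments. The pruning threshold 0.6 separates the two
  regimes observed in practice — within-compound correlations near 1
  versus chance correlations of independent channels (about ±0.2 at the
  cohort sizes involved) — with a wide margin on both sides. A
  fixed threshold on loadings themselves proved fragile (values 0.77 vs
  0.80 across the two regimes).

Degenerate inputs: a constant fragment has no correlation structure and
always becomes its own compound; a window with a single fragment is a
singleton; with fewer than 3 samples correlation is undefined and every
fragment is kept separate, with a warning.

VOC intensity is the per-sample **sum** of member-fragment counts (on raw
counts — summation must happen before any log transform), the retention
centroid is the total-count-weighted mean of member retention times, and
the grand total ion count is conserved exactly.

# Univariate screening

Per VOC, cases and controls are compared with a two-sided Wilcoxon
rank-sum test (exact enumeration when both groups have ≤ 8 observations
and no ties; otherwise the normal approximation with tie and continuity
correction). The effect size is the median fold change with a pseudocount
of 1 on both medians, protecting against zero medians; on realistic ion
counts (10³–10⁵) the pseudocount is negligible. Discrimination is the
Mann–Whitney AUROC; since discriminative breath compounds can be *lower*
in cases, the direction-agnostic value `max(A, 1 − A)` is used for the
gate and reported alongside the directed value. The selection gate is
`p < 0.05` **and** direction-agnostic AUROC `> 0.7`; both thresholds are
arguments. No per-VOC multiple-testing correction is applied — the
family-level control is the permutation assessment below. Two contrasts
are defined: `pneumonia` (probable cases vs controls, the two intermediate
groups dropped — two clean groups at the extremes of the disease
spectrum) and `culture` (positive vs negative over the full cohort).

**Permutation false discovery.** The labels of the chosen contrast are
permuted (default 1000 times) and the screen is recomputed per
permutation with a vectorised rank-based implementation (ranks are
label-free, so each permutation is a single matrix product; the
closed-form normal-approximation p-values are tested against
`wilcox.test` to 1e-12). The per-permutation family summary is the *best
VOC*: minimum p-value and maximum direction-agnostic AUROC. The reported
fractions are the proportion of permutations with a similar-or-better
summary (p ≤ observed, AUROC ≥ observed). "Similar or better" admits
other summaries; the count of gate-passing VOCs is available via
`statistic = "count"`. The best-VOC summary was made the default because
it is the natural family-level statistic for "could our top finding arise
by chance".

# PCA and PLS-DA

**Preprocessing.** Intensities are `log2(x + 1)`-transformed and
autoscaled per VOC (mean 0, SD 1). The transform tames the right skew of
count data; autoscaling stops abundant compounds from dominating the
latent space. Preprocessing parameters are always *frozen on the training
set* and applied unchanged to held-out samples; a constant VOC gets SD 1.
Results depend on this choice, which is why it is centralised in
`preprocessIntensities()` and stored inside every fit.

**PCA.** SVD on the centered standardized matrix of gate-selected VOCs
(configurable to all VOCs); variance fractions are squared singular
values over their total; per-component case/control score differences are
tested with the same Wilcoxon machinery. Components with singular value
below `1e-12` times the largest are dropped.

**PLS-DA.** A NIPALS PLS1 fit of the centered 0/1 class code: per
component, weight `w = X'f/‖X'f‖`, score `t = Xw`, loadings
`p = X't/t't`, `q = f't/t't`, deflation `X ← X − tp'`, `f ← f − qt`;
coefficients `B = W(P'W)⁻¹q`. Two components by default, matching common
practice of displaying two latent dimensions; the count is capped by the
training rank, and components with numerically zero score variance are
dropped (tolerance 1e-12). The predicted probability is the linear
prediction `ȳ + XB` clamped to [0, 1] — with no stated link function,
the clamped identity is the most transparent choice; a sample at the
training feature mean receives the training prevalence. Known identities
used as test oracles: the first weight is proportional to `X'(y − ȳ)`,
and at full rank the coefficients equal the least-squares solution.

# Cross-validation and extrapolation

Leave-one-out cross-validation repeats **everything** inside each fold:
the held-out sample is removed, the dual-gate screen is re-run on the
remaining samples, preprocessing parameters are recomputed, the PLS-DA
model is refitted, and only then is the held-out sample predicted. This
is the construction that makes the in-set vs cross-validated AUROC gap an
honest measure of selection-induced optimism. If a fold's gate selects
nothing, the five smallest-p VOCs are used and the event is counted and
messaged (`nFallback`); this keeps every fold defined without silently
changing the gate. AUROC confidence intervals use the DeLong variance of
the placement values with a normal 95% interval clipped to [0, 1].
Confusion matrices call a sample a case at probability ≥ 0.5 (threshold
exposed); rows are predicted, columns true, so column margins equal the
true class counts — a consistency check `buildStudyReport()` enforces.

The case/control-trained model is finally applied to the two intermediate
groups (colonized without pneumonia, possible pneumonia), which it never
saw. Their probability distributions, displayed in spectrum order
control → colonized → possible → probable, show where the model places
patients between the two extremes.

# The synthetic cohort

`simulateBreathDataset()` emulates the statistical structure of a
four-group ventilated-ICU breathomics cohort. Parameters, units and
defaults:

| parameter | default | meaning |
|---|---|---|
| `nPerGroup` | 47/13/21/12 | control / colonized / possible / probable group sizes |
| `nVocs` | 145 | disease-related compounds |
| `nInformative` | 11 | VOCs carrying the planted effect |
| `effectLog2` | 2 | log2 *decrease* in probable-pneumonia cases |
| `intermediateFraction` | 0.5 | fraction of the effect in the two intermediate groups |
| `fragmentsPerVoc` | (1, 6) | uniform fragment fan-out per VOC |
| `rtJitter` | 1 s | uniform fragment jitter around the VOC centroid |
| `noiseSigmaLog` | 0.5 | SD of per-sample biological variation, log2 scale |
| `fragmentNoiseSigma` | 0.05 | SD of per-fragment measurement noise, log2 scale |
| `nContaminants` | 5 | exogenous, disease-independent channels |

Intensities are log-normal (counts are positive and right-skewed;
multiplicative noise is the standard default when no distribution is
reported): a VOC's latent log2 abundance is its baseline (uniform 8–16,
i.e. counts of roughly 250–65000) plus the group effect plus
`N(0, noiseSigmaLog)`; a fragment's count is the abundance times a fixed
response factor (uniform 0.2–1) times `2^N(0, fragmentNoiseSigma)`,
rounded to a non-negative integer. Fragments of one VOC are therefore
strongly correlated — the premise of the aggregation rule. The planted
effect is a *decrease* in cases, the direction reported for discriminative
breath compounds in this setting; the intermediate groups receive a
configurable fraction (default half) so that extrapolated probabilities
order the clinical spectrum. Contaminant channels model compounds of
exogenous origin (anaesthetics, solvents): single fragments, high
variance (SD 1.5 log2), independent of disease. Culture status is
deterministic in its margins — all colonized patients positive, and
positives in the possible/probable groups scaled from the reference
cohort proportions (3/21 and 9/12), giving 25 positives at default sizes.
VOC centroids are spaced by uniform 10–14 s gaps, so inter-VOC windows
are disjoint by construction; the RNG consumption order is documented in
`?simulateBreathDataset` and reproducible bit-for-bit from the seed.

Defaults for effect size and noise are free choices — no intensity
distribution or effect magnitude is available to copy — set once at
"clearly detectable effect" (fourfold, 4 SD at default noise) and
documented here. What the simulator deliberately does **not** emulate:
chromatographic peak shapes and tailing, m/z values, batch and drift
effects, heteroscedastic detector noise, missingness, correlated VOC
panels (each VOC is independent given its group), or label noise in the
clinical reference standard. Passing tests on this generator therefore
validate the *statistical machinery* — recovery, calibration, leakage
control — not performance on real cohorts, where effect sizes are smaller
and the reference standard is imperfect.

# Numerical and testing choices

* Ion-count conservation through aggregation is asserted to 1e-9
  relative; statistical primitives are tested against independent oracles
  (brute-force pair counting for AUROC, full enumeration for the exact
  Wilcoxon branch, eigendecomposition for PCA variance, the analytic
  first-weight identity and the least-squares limit for PLS) at 1e-9.
* Stochastic properties use fixed seeds and these problem sizes: null
  calibration of the permutation fractions with 200 replicate cohorts at
  99 permutations each (empirical CDF at 0.05 within 3 binomial SD);
  planted-effect recovery and the optimism direction (in-set ≥ LOOCV on
  null data) averaged over 10 seeds at the default cohort size; spectrum
  ordering of extrapolated probabilities averaged over 10 seeds.
* Unit tests run on a reduced cohort (25 samples, 20 VOCs) so the suite
  stays fast; the acceptance suite exercises the full default cohort.

# Limitations

* The aggregation rule assumes within-compound fragment correlation well
  above `minCor`; heavy censoring or detector saturation would violate
  this and fragment a compound into several features.
* The permutation assessment permutes labels freely and therefore assumes
  exchangeability under the null; it does not model confounding
  covariates.
* LOOCV on 59 samples with 12 cases has high variance; the DeLong CI on
  pooled held-out probabilities ignores the dependence between folds, a
  standard but optimistic simplification.
* PLS-DA probabilities are clamped linear predictions, not calibrated
  posteriors; threshold-based confusion matrices inherit this.
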