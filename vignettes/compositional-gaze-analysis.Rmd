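---
title: "Compositional analysis of AOI dwell times: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of AOI dwell times: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecoda)
```

## The data and the two tracks

The unit of analysis is a vector of total fixation durations (TDoF, in ms)
that one participant accumulated in each of D Areas of Interest while
solving one task. Such a vector mixes overall viewing pace with the
allocation of attention across regions. gazecoda therefore runs two
parallel tracks over the same tables:

* the **compositional track** treats each row as a composition — a strictly
  positive vector whose information content is the set of ratios between
  parts — and works in log-ratio coordinates;
* the **classical track** analyses the raw milliseconds with ordinary
  multivariate tools (arithmetic means, Pearson correlations, Euclidean
  PCA/clustering, MANOVA and LDA on the raw responses).

Comparing the two tracks on the same data is the point, not a redundancy:
statistics on the compositional track are invariant to per-row rescaling
(the package tests this with multipliers drawn per row), while every
classical statistic moves when totals change. Which track answers the
scientific question depends on whether viewing pace is signal or nuisance.

## The log-ratio kernel

For a row `x` with geometric mean `g(x)`:

* clr: `y_j = ln(x_j / g(x))`; rows sum to zero, so the clr covariance is
  singular — clr is used for description, PCA and clustering, never for
  full-rank inference.
* ilr pivot coordinates: `z_j = sqrt((D-j)/(D-j+1)) ln(x_j / gm(x_{j+1..D}))`,
  j = 1..D−1, an isometric, orthonormal basis of the clr hyperplane. All
  inferential results (MANOVA statistics, discriminant assignments) are
  invariant to the pivot order; the package accepts any permutation and the
  test suite asserts the invariance to 1e-9 (exactly, for class
  assignments).
* Aitchison distance: the Euclidean distance between clr images; the metric
  behind observation clustering.
* Variation matrix `t_jk = var(ln(x_j/x_k))` with total variance
  `(1/2D) Σ t_jk`, algebraically equal to the sum of clr coordinate
  variances and to `Σ λ_k² / (n−1)` over the clr-PCA singular values. All
  three routes are computed and compared in the tests.

**Variance divisor.** Sample variances use the unbiased divisor n−1
everywhere, with a `divisor = "ml"` switch (divisor n) on
`variation_matrix()` and `total_variance()`. Published totals computed under
the other convention differ by the factor (n−1)/n — about 0.7% at n = 144 —
which is worth remembering when comparing third decimals against printed
tables.

**Zeros.** An unvisited AOI produces a zero, and log-ratios require strict
positivity. The default policy replaces each zero in AOI column j by 0.65
times the smallest positive value in that column — a deliberately simple
multiplicative-style imputation; the replacement count is logged and
attached to the result. A column with no positive entries cannot be imputed
and is rejected with the advice to merge that AOI into a neighbour
(`aggregate_aois()` conserves row totals exactly). Merging is generally the
sounder remedy for systematically sparse regions; imputation is for
occasional zeros.

## Multivariate methods

**PCA.** `coda_pca()` decomposes the column mean-centred clr matrix (or the
centred raw matrix in classical mode) by SVD. Scores are `U D`, loadings the
right singular vectors. Explained-variance shares are computed from λ²
(`explained`), since only squared singular values satisfy the
total-variance identity; the λ-proportional shares are also exposed as
`explained_sv` for comparison with software that reports them. Only
non-null components are returned (at most min(n−1, D−1) in clr mode): the
trailing SVD directions span the null space with an arbitrary basis and
would, in clr mode, violate the zero-sum property of genuine log-contrast
loadings. The SVD sign ambiguity is fixed by flipping each loading so its
largest-magnitude entry is positive, making results reproducible across
BLAS implementations. `biplot_links()` returns the squared vertex-to-vertex
distance for a pair of parts: with all components retained it equals the
variation-matrix entry exactly; truncation to the displayed components can
only shrink it.

**Clustering.** Complete linkage throughout — the merge criterion is the
distance between farthest members. Observations are clustered on clr
coordinates (Aitchison metric) or raw ms; AOIs are clustered on the
variation matrix, using `t_jk` itself as the dissimilarity (a `use_sqrt`
flag gives the metric variant). The agglomeration is delegated to
`stats::hclust`, whose deterministic ordering provides the tie-break; the
test suite verifies the heights against a brute-force farthest-neighbour
scan on small instances under both metrics.

**MANOVA.** The group model in the simplex — each observation is the group
mean perturbed by logistic-normal noise — becomes an ordinary Gaussian
MANOVA after the ilr map. `coda_manova()` forms the between- and
within-group cross-product matrices and computes Pillai's trace
`V = tr(B (B+W)^{-1})`, the standard F approximation with
`s = min(p, K−1)`, `m = (|p−K+1|−1)/2`, `n* = (N−K−p−1)/2`,
`df = (s(2m+s+1), s(2n*+s+1))`, and partial `η² = V/s`. For the study-sized
design (K = 7, D = 7, N = 1008) these give (36, 6006) on the compositional
track and (42, 6000) on the classical track. The implementation is checked
against `stats::manova` to 1e-9 and against a Hotelling-T² computation in
the two-group case, where the approximation is exact. Pairwise tests over
all K(K−1)/2 task pairs are Holm-corrected; the step-down is written out in
the package (sorted p's scaled by m−i+1, cumulative max, capped at 1) and
verified against `p.adjust`.

**Task effects.** For a complete balanced design (every participant ×
every task), the fixed task effects of a random-intercept mixed model have
a closed form: centre each participant's values at their own across-task
mean, then average the deviations per task. `clr_task_effects()` implements
exactly that, on the clr coordinate of one AOI (effects are multiplicative:
`exp(effect)` is the dominance factor relative to the participant's own
mean) or on raw ms (additive). Unbalanced data are rejected rather than
approximated — an explicit mixed-model fit is the right tool there and out
of scope here.

**Classification.** `fit_discriminant()` implements Bayes' rule on Gaussian
class densities of the ilr (or raw) coordinates. LDA pools the covariance
with divisor N−K; QDA estimates per-class covariances with divisor n_k−1;
priors default to empirical class shares (equal under a balanced design).
Posteriors are normalised per observation. Cross-validation stratifies fold
assignment by task: each task's rows are shuffled under the caller's seed
and dealt round-robin, so the report is a deterministic function of the
seed. Folds are drawn at the observation level, so the 7 rows of one
participant can straddle train and test; with participant random effects
this leaks a little identity information across the split, which is worth
keeping in mind when reading absolute accuracies. (Participant-grouped
folding would be the stricter alternative; it is not implemented because
the effect on the synthetic benchmarks is small relative to seed noise.)

## The synthetic generator

`simulate_experiment()` generates the table the analysis assumes: for
participant i and task k, the ilr image of the composition is
`z_ik = ilr(μ_k) + p_i + e_ik` with `p_i ~ N(0, σ_p² I)` shared across a
participant's rows and `e_ik ~ N(0, σ_e² I)` independent — a
logistic-normal model, which is precisely the distribution under which the
compositional MANOVA's normality assumption holds. The composition is then
scaled to a lognormal total time, which carries no compositional
information at all; multiplying all totals by any constant changes no
compositional statistic and every classical one (asserted both ways in the
tests).

Defaults: `σ_p = 0.3`, `σ_e = 0.5` (ilr standard deviations), totals
lognormal(ln 15000, 0.5) ms, 144 participants, 7 tasks × 7 AOIs. With
these scales the per-task total variance is about
`(σ_p² + σ_e²)(D − 1) ≈ 2.0` — a moderately noisy experiment in which task
structure is clearly detectable but individual rows overlap. The
`task_means_yarbus()` preset encodes, in deliberately round illustrative
numbers, the classic task-dependence pattern: a large Background share
under free viewing, Furniture nearly ignored in the person-focused tasks
(3, 5, 7), children dominating task 4, and the returning man above half the
time in task 7. `simulate_null()` gives every task the same mean (by
default the pooled seven-AOI composition) for type-I-error and chance-level
harnesses; `inject_zeros()` zeroes random cells (never a whole row) to
exercise the zero policy.

What the generator does **not** emulate: temporal structure within a trial
(scanpaths, fixation sequences), heavy-tailed or skewed noise beyond the
logistic-normal family, task-order or learning effects, participant-level
covariates, and structurally sparse AOIs whose zeros are informative rather
than random. Tests passing on this generator therefore certify the
statistical machinery under its stated assumptions, not robustness to every
feature of real gaze data.

## Numerical choices and degenerate inputs

* Tolerances: 1e-10 for exact algebraic identities (clr zero-sum, closure),
  1e-9 for round-trips and cross-implementation comparisons; both are
  package constants, not per-test fudge factors.
* Natural logarithms throughout; closure defaults to κ = 1 internally and
  κ = 100 for display tables.
* Rank problems fail loudly: a MANOVA or LDA covariance made singular by
  proportional parts is rejected with the advice to merge AOIs, not
  silently regularised.
* Rows with zero total dwell time carry no relative information and are
  dropped with a warning during reshaping; missing (participant, task, AOI)
  cells are completed as flagged zeros so the validation report can surface
  them.

## Problem sizes in the test suite

The simulation-based checks run at sizes chosen to keep Monte-Carlo error
well inside the asserted bands: 2000 null replicates of a 3-group,
4-part MANOVA (n = 20 per group) for the type-I rate and p-value
uniformity; 200 participants × 7 tasks for chance-level cross-validation
(1400 rows); 200–1000 rows for mean and effect recovery, where tolerances
of 2–3 percentage points per part correspond to roughly 1.5–4 Monte-Carlo
standard deviations under the default noise scales. Full-study-shaped runs
(144 × 7 × 7) exercise the df arithmetic and the pipeline end to end.

## Known limitations

* The balanced-design effect estimator covers complete designs only.
* Zero handling is the simple column-minimum fraction rule; model-based
  imputation is out of scope.
* No robust (outlier-resistant) estimators: a single wild row influences
  means, variation matrices and PCA as it would in any Gaussian-likelihood
  method.
* Cross-validation folds are observation-level, as discussed above.
* The ternary display requires exactly three parts; aggregate first.
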