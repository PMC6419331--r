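---
title: "Methods: multiple imputation and moderated linear models for peptide-centric proteomics"
author: "promi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple imputation and moderated linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promi)
```

# The problem

Peptide-centric label-free quantification, especially after enrichment
for a post-translational modification such as reversible cysteine
oxidation, produces abundance tables with two awkward properties: a very
large dynamic range, and missing values that arise from at least two
different mechanisms. Some cells are missing for reasons unrelated to
their value (failed matching, alignment dropouts — missing at random,
MAR/MCAR); others are missing *because* the underlying abundance was too
low to be detected (left-censoring — missing not at random, MNAR).
Treating censored cells as if they were randomly missing biases
fold-change estimates upward for low-abundance peptides; discarding every
feature with a missing value discards exactly the low-abundance,
biologically interesting part of a PTM dataset.

`promi` implements a pipeline that (1) pre-processes peptide-measurement
exports into unique-identifier feature tables, (2) imputes missing data
from normal distributions with robustly estimated parameters under an
explicit MAR/MNAR split, (3) fits per-feature linear models with
empirical-Bayes variance moderation, and (4) converts the instability of
imputation into a decision procedure: the analysis is repeated over many
imputed datasets and a feature is only called significant if it is
significant in more of them than a fair coin could explain.

# Pre-processing

The input is a CSV export with one row per matched MS1 feature (peptide
sequence, modifications, identification score, protein accession,
per-sample abundances in area-under-curve units). The chain is:

1. **Score and contaminant filtering.** Rows with an identification
   score below 13 are removed (the conventional Mascot cutoff; the
   boundary itself is kept, `score >= 13`), as are accessions matching a
   configurable contaminant prefix list (default `CONTAM_`, `sp|CON` —
   contaminant databases differ between laboratories, so the list is a
   parameter rather than a constant).
2. **Parsimony resolution.** Duplicate rows of one feature that differ
   only in protein accession are collapsed to the accession supported by
   the most unique peptides; ties fall back to the higher protein
   confidence score, and a double tie keeps the lexicographically
   smallest accession with a warning. The deterministic fallback is a
   design choice: reproducibility beats arbitrariness, and the case is
   rare enough that a warning suffices.
3. **Feature deduplication.** A feature carrying several alternative
   peptide identifications keeps the highest-scoring one; an exact score
   tie keeps the lexicographically smallest sequence, again with a
   warning.
4. **PTM filtering** (Cys-oxidation mode only). Reduced cysteines are
   carbamidomethylated before enrichment, so a cysteine *without* that
   modification marks a site of reversible oxidation; peptides with no
   such cysteine are removed.
5. **Identifier construction.** Global mode concatenates accession and
   peptide sequence; PTM mode joins the accession with the Cys site(s).
   When the export carries a peptide start coordinate, sites are
   expressed in protein coordinates (`start + offset − 1`); otherwise
   peptide-local offsets are used and the table is flagged
   (`metadata()$localCysCoords`), because export dialects differ in
   whether they carry protein coordinates at all. Duplicate identifiers
   (charge states, missed cleavages, modification combinations) are
   binned by summing abundances per sample. A summed cell is missing
   only when *every* contributor is missing; missing contributors
   otherwise count as absent rather than zero — summation should not
   invent values. Each identifier is represented by its highest-scoring
   contributor.

Filtering is monotone and deterministic: the same file always yields the
same table.

# The imputation model

Let `x_ij` be the vector of observed log2 abundances of feature *i* in
condition *j*, with `r` observed replicates.

* `μ̂_ij`: the mean of the observed values of the cell vector, defined
  whenever `r ≥ 1`.
* `σ̂_j`: the median of the per-feature sample standard deviations
  (n−1 denominator) over the features *fully observed in condition j*.
  The subscripting matters and was a genuinely open reading: the
  pool could plausibly be features complete everywhere. We use
  complete-in-that-condition, which keeps the estimate local to the
  condition whose cells are being imputed and uses strictly more
  features. Features with a single replicate in a condition have no
  sample SD and are excluded. If a condition has *no* fully observed
  feature, the median of SDs pooled across all conditions is
  substituted with a warning (or an error, if the fallback is disabled)
  — real datasets essentially never hit this branch, but simulated
  worst cases do.
* `μ̂_MNAR = Q1(V) − 1.5 · (Q3(V) − Q1(V))`: the lower Tukey fence of
  the pooled vector `V` of *all* observed log2 values.

A missing cell is drawn from `N(μ̂_ij, σ̂_j)` when `r ≥ 1` and from
`N(μ̂_MNAR, σ̂_j)` when `r = 0`. The rationale for the MNAR mean: if all
replicates of a feature in a condition are undetected, the most likely
explanation is an abundance below the detection limit, so draws are
centred below essentially all observed data — the lower fence is a
robust "just below the data" location that degrades gracefully (for a
constant dataset it equals the constant).

**Quantile convention.** Q1 and Q3 use linear interpolation between
order statistics (R's default, type 7), fixed throughout: changing the
convention changes `μ̂_MNAR`, so it is part of the model definition, is
recorded in the serialized metadata, and is pinned by a test against a
manual order-statistic oracle (`V = [1,2,3,4]` gives `μ̂_MNAR = −0.5`).

**Outlier-feature removal.** Before estimation, features whose *every*
observation lies strictly outside the pooled fences
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` are dropped. The fences could be global,
per-sample, or per-feature; we use global fences over all pooled log2
values, the same pooled vector that defines `μ̂_MNAR`, to keep one
convention throughout. A single in-fence observation saves a feature,
and values exactly on a fence are not outside (so an IQR of zero drops
nothing).

**Zero or negative raw abundances** are rejected by default with an
error naming the identifier and sample; `zeroAsMissing = TRUE` converts
exact zeros to missing before transforming, for exports that encode
missingness as 0.

**Randomness.** The generator is pinned (Mersenne-Twister, inversion
normals). Multiple imputation derives per-draw seeds as
`masterSeed + i`, records them in the `ImputedSet`, and never perturbs
the caller's RNG state. Identical seeds give identical matrices;
observed cells are bit-identical across all imputations.

# Moderated linear models

Each completed matrix is fitted per feature under cell-means coding (one
coefficient per condition), so a contrast's log2 fold change is a
difference of condition means. The parameterization is a design choice —
any full-rank coding gives the same contrasts, and cell-means keeps every
reported quantity directly interpretable.

The **robust** option replaces OLS with Huber M-estimation by
iteratively reweighted least squares: weights `min(1, c·s/|resid|)` with
`c = 1.345` (95% efficiency at the normal), per-feature scale `s`
re-estimated each iteration as the MAD of the residuals, at most 20
iterations, convergence when no coefficient moves more than 1e−6.
Non-convergence falls back to the last iterate with a warning. When all
weights are 1 the robust fit coincides exactly with OLS, which is pinned
by a test. The residual variance is the weighted
`sum(w·r²)/(sum(w) − M)` on `n − M` df.

**Empirical-Bayes moderation** follows the classical closed forms: with
`e = log(s²) − digamma(d/2) + log(d/2)`, the excess variance
`var(e) − trigamma(d/2)` estimates `trigamma(d₀/2)`, inverted by Newton
iteration; `s₀² = exp(mean(e) + digamma(d₀/2) − log(d₀/2))`. The
posterior variance `(d₀s₀² + ds²)/(d₀ + d)` always lies between `s²` and
`s₀²`. Moderated t-statistics are referred to a t distribution on
`d₀ + d` df, capped at the pooled residual df of the ensemble; when the
moment estimate is non-positive, `d₀ = ∞` and the prior is the mean
sample variance. Exact-zero variances are offset to `1e−5` times the
median variance before taking logs. These choices — including the df cap
and the offset — reproduce the reference implementation of the moderated
t to 1e−6 on seeded data, which the test suite checks against limma
directly. No variance trend, no winsorization, no
proportion-of-DE adjustment: the plain moderated t.

p-values are two-sided and Benjamini–Hochberg adjusted per contrast.

The **t-test baseline** used in benchmarking is a per-feature Welch
(unequal-variance) two-sample t-test on a single imputed dataset, BH
adjusted, with LFC the difference of condition means. When both group
variances are exactly zero the statistic is undefined; we set p to 0
when the means differ and 1 when they are equal, with a warning. This
degenerate rule preserves the ordering of decisions on synthetic data
with exact ties and never triggers on continuous real data.

# The binomial decision

Per imputation, a feature succeeds when its adjusted p-value is below
`α` *and* its LFC is beyond the cut-off (strictly above `lfcUp`, or
strictly below `lfcLow`; `lfcLow = −Inf` disables the decreasing side,
the right setting for spike-in designs where all true changes increase).
Strict inequalities follow the natural reading of "below α, above the
cut-off"; with continuous statistics the choice is measure-zero.

Whether the per-imputation criterion should use raw or adjusted
p-values was open; we use FDR-adjusted p-values — consistent with the
correction being part of the per-dataset analysis — and expose
`useAdjusted = FALSE` as a switch.

The final call is the exact right tail `P(X ≥ k)` for
`X ~ Binomial(n, 0.5)` (the tail includes `k`), significant below a
decision level of 0.05. At `n = 100` the critical count is `k* = 59`
(`P(X ≥ 59) ≈ 0.0443`, `P(X ≥ 58) ≈ 0.0666`). Note the vote is
meaningless for `n = 1` (the tail at `k = 1` is 0.5): single-dataset
methods use the plain hybrid threshold (`singleDecision()`). The pooled
effect size reported per feature is the mean LFC across imputations —
the standard multiple-imputation pooling of a point estimate; no
Rubin's-rules variance pooling is attempted because the decision is the
binomial vote, not a pooled t-test.

# Evaluation protocol

Truth labels are a function of accession origin only (spiked proteome =
TP, background = TN), never of any decision output. Confusion rates are
`FPR = FP/(FP+TN)` and `TPR = TP/(TP+FN)`, reported ×100. Threshold
grids are ten points with `α` from 0.05 down to 0.001 and the LFC
cut-off from 0 up to 2, varied separately or in lockstep; whether the α
grid should be linear or logarithmic is not determined by the protocol
we emulate, so we use linear spacing for both axes and record the grid
in the output, making alternative spacings comparable. ROC points are
reported as discrete operating points; no interpolation or
area-under-curve, since operating points are what the decision procedure
actually produces. The filtering baseline (`dropMissing = TRUE`)
removes every feature with at least one missing cell before analysis;
when comparing against it, dropped features count as not-called, so
confusion totals stay constant.

# The synthetic spike-in generator

Because the benchmark mass-spectrometry datasets are not redistributable
at package scale, `promi` ships a generator that emulates the two
designs as presets, with known truth:

* **`ups1-like`** (global proteome): 10,000 background + 400 spiked
  features, three conditions at relative concentrations 25/50/100
  (fmol-like) × 4 technical replicates. Sparse missingness:
  `mcarRate = 0.003`, censoring threshold 12.9 on the log2 scale, which
  empirically produces ≈0.75% missing cells concentrated in ≈4.6% of
  features — matching the sparse-missingness regime of a global
  proteomics experiment.
* **`yeast-ptm-like`** (Cys-oxidation enrichment): 1,780 background +
  450 spiked features, two conditions (50/100, ng-like) × 3 replicates,
  noisier (replicate SD 0.4 vs 0.25), with `mcarRate = 0.015` and
  censoring threshold 15.8 — ≈7.3% missing cells in ≈20% of features,
  the heavy-missingness regime typical of enrichment protocols.

Baseline log2 abundances are drawn per feature from `N(18, 2.2)`:
area-under-curve intensities in label-free experiments span roughly
15–25 on the log2 scale with an interquartile width of a few log2 units,
and drawing spike baselines from the same distribution makes some true
positives intrinsically hard (low-abundance spikes near the censoring
limit), which is what makes the ROC comparison informative. Spiked
features are shifted by `log2(conc_j / conc_1)`, so their expected LFC
between conditions is the log concentration ratio; background features
have expected LFC 0. Missingness is injected after generation: random
dropout first, then left-censoring of every cell below the threshold,
with the mechanism of each removed cell recorded in a map. Features
losing all cells are dropped with a message.

What the generator does **not** emulate: correlated peptides from the
same protein, retention-time alignment artefacts, intensity-dependent
variance beyond the censoring itself, identification errors, or batch
structure. Passing benchmarks on this generator therefore demonstrates
the statistical machinery under the stated missingness model, not
robustness to every pathology of real MS data.

# Problem sizes and numerical checks

The test suite verifies, among others: Kolmogorov–Smirnov agreement of
10,000 imputed draws with the fitted normals (MAR and MNAR) at the 1%
level; the `μ̂_MNAR` closed form against a manual quantile oracle; the
binomial critical value `k* = 59` at `n = 100` against brute-force pmf
summation; moderated t and p against limma to 1e−6 on a seeded 200 × 8
matrix; type-I error of the moderated test within binomial 99% bounds on
5,000 pure-null features; and the headline comparison — 20 replicate
`ups1-like` simulations at full preset size with 100 imputations each,
requiring the pipeline's TPR to be at least the t-test's at the majority
of matched grid cells in the majority of simulations, plus the strict
TP gain of imputation over filtering on a `yeast-ptm-like` dataset.
These sizes keep the full suite under a few minutes while leaving the
stochastic checks enough resolution to fail if the machinery drifts.

# Known limitations

* `σ̂_j` is a single per-condition SD; no per-feature or
  intensity-dependent variance model is attempted beyond what moderation
  provides downstream.
* The MNAR model is a point-mass location shift (all censored cells
  share one mean); a principled censored-likelihood model would use the
  threshold itself.
* The binomial vote treats imputations as exchangeable trials; it is
  deliberately conservative for features whose significance is driven by
  imputed cells.
* Random-forest or k-NN imputation engines are out of scope; externally
  produced decision tables in the ROC TSV schema can be evaluated with
  the same grid machinery for such comparisons.
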