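---
title: "winescape: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{winescape: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what the models are, what they assume, which knobs matter, what the
synthetic data do and do not emulate, and where the design was genuinely
open.

## 1. The trait model on the tree

A quantitative trait evolving by Brownian motion along a rooted phylogeny
induces a Gaussian distribution over tip values with mean μ (the root
state) and covariance σ²C, where C_ij is the depth of the most recent
common ancestor of tips i and j (`bm_covariance()`). Pagel's λ interpolates
between this model and phylogenetic independence by multiplying the
off-diagonal of C by λ ∈ [0, 1] (`lambda_transform()`): λ = 1 is Brownian
evolution, λ = 0 makes tips independent with their original variances.

For fixed λ, μ and σ² have closed-form maximum-likelihood profiles
(generalised least squares for μ, the scaled quadratic form for σ²), so the
likelihood is profiled to a one-dimensional function of λ
(`profile_loglik()`). `estimate_lambda()` maximises it with a 21-point grid
pre-scan followed by bounded scalar optimisation around the grid optimum;
the pre-scan matters because the profile can be multimodal, and the
estimate is checked against both endpoints. Estimation is ML, not REML,
matching the convention of the standard phylogenetic-signal tools.

Significance (`lambda_significance()`) is a permutation test: trait values
are shuffled across tips, λ is re-estimated per shuffle, and
p = (1 + #{λ_perm ≥ λ̂}) / (1 + n_perm). The add-one correction keeps p
away from zero; ties count against significance. One consequence worth
stating plainly: under a true null, λ̂ frequently sits exactly on the 0
boundary, where every permutation ties or exceeds it and p ≈ 1. The test is
therefore *conservative* — P(p ≤ α) ≤ α — rather than uniform under the
null, and the test suite asserts exactly that calibration property plus the
empirical type-I error at α = 0.05 (observed within [0.01, 0.09] over 200
null simulations).

Assumptions: the tree is ultrametric (checked on read with tolerance
10⁻⁶ × height; violations are warned about, never silently repaired,
because chronogram output commonly carries rounding error), branch lengths
are in consistent units, and traits are continuous. Strains with identical
marker sequences appear as zero-length splits; at λ = 1 these make C
singular, which is handled by a ridge of 10⁻¹⁰ × tree height with a
warning.

### Numerical note

For an ultrametric tree all diagonal entries of C equal the height h, so
C(λ) = λC + (1−λ)hI shares the eigenbasis of C for every λ. The estimator
eigendecomposes C once and evaluates each profile point in O(n) after an
O(n²) projection of the trait vector. This is what makes 1,000-permutation
tests over 43 traits, and the 200-replicate null calibrations in the test
suite, cheap. Non-ultrametric covariances fall back to a per-λ Cholesky
factorisation.

## 2. Imputation and its cross-validation

`impute_tips()` predicts a missing tip as the conditional expectation of
the Gaussian trait model given the observed tips, with μ replaced by its
GLS estimate; the predictive variance is the conditional variance plus the
propagated uncertainty of the estimated mean. This equals rerooting the
phylogeny at the missing tip's attachment node and running
Felsenstein-pruning ancestral reconstruction — the test suite verifies the
identity against an independent message-passing implementation to 10⁻⁸.
Imputation is per-trait (univariate) under pure Brownian motion by default;
a trait-specific λ can be plugged in via the `lambda` argument. A
multivariate model that borrows strength across traits would be a natural
extension but would have no comparably simple independent oracle, so it is
deliberately out of scope.

`loocv_impute()` removes, for each focal strain, all trait values of an
exclusion set before predicting: the strain itself, its identical-marker
group (derivable from zero cophenetic distances when metadata lacks it),
its species, or its genus. Accuracy is the Pearson correlation between
predicted and observed values per trait, on the original trait scale.
A single remaining observation still defines a prediction (the GLS mean of
one point is that point); predictions resting on a single observed strain
are flagged with a warning rather than dropped, since the genus-level
analysis of a lopsided collection legitimately produces them.

## 3. Community function and functional effect equations

Community function is the fraction of initial fermentable sugars consumed,
F = (initial − residual)/initial, clipped to [0, 1]
(`community_function()`; initial = 200 g/l glucose + fructose in synthetic
grape must). Replicates are aggregated by arithmetic mean; standard
deviations are kept for reporting only, and the FEE fits are unweighted
ordinary least squares — plain linear fits of

ΔF_i(B) = a_i + b_i·F(B) + θ_i(B)

over every measured (B, B ∪ {i}) pair (`fit_fee()`, minimum 3 pairs). The
empty community is a hard anchor at F = 0, which gives each monoculture the
pair (∅, {i}). The residual variance σ_i² = SSR/(n−2) is floored at 10⁻⁴ on
the [0, 1] function scale so a zero-residual fit cannot produce infinite
edge weights downstream.

### Predicting unmeasured communities

`predict_function()` concretises the concatenation-of-FEEs idea as weighted
least squares on the subset lattice. For target c_t it takes c₀ = the
largest measured subset of c_t (ties broken by replicate count, then
lexicographically), builds all nodes c₀ ⊆ S ⊆ c_t plus any other measured
subsets of c_t, fixes measured nodes at their replicate means, and solves

min Σ over edges (S, S∪{i}) of (F_{S∪i} − (1+b_i)·F_S − a_i)² / σ_i²

for the latent node values — a small dense linear system. This estimator
provably satisfies the two contracts the concatenation idea demands: the
result does not depend on the order in which species are "added" (the
objective is a set function; the suite checks 20 random member
permutations agree to 10⁻⁹), and when exactly one lattice edge reaches the
target it reduces to the closed form F(c₀) + a_C + b_C·F(c₀). When several
measured sub-communities exist, the predictor deliberately fuses all paths
(inverse-variance weighting) instead of picking one — with more than one
edge into the target the prediction is a precision-weighted compromise, not
the single-path formula. In-sample targets are returned at their observed
means exactly. Predictions are clipped to [0, 1] with the raw value
retained, since function is a fraction by construction. `scope =
"powerset"` (every subset of the target) is available for sensitivity
analysis; the interval scope is the default because nodes below c₀ add
latent variables without adding information about the target.

The additive baseline (`additive_predict()`) is
F = F_focal + Σ_i ΔF_i with ΔF_i the pairwise effect of strain i in
co-culture with the focal strain; it ignores all context dependence, which
is exactly why its error grows with community richness. "Prediction
accuracy" per community is reported both as squared error and absolute
error (`evaluate_predictions()`), with RMSE overall and per richness.

## 4. The synthetic-data generator

`simulate_collection()` emulates a wine-yeast panel: a pure-birth
(Yule) tree rescaled to height 1; a few cherries collapsed to zero terminal
length (the branch length moved onto the stem, keeping the tree
ultrametric) to stand in for strains with identical 26S marker sequences;
traits drawn from N(μ, σ²C(λ)) with per-trait λ sampled from a grid; and
taxonomy assigned by cutting the cophenetic dendrogram at fixed heights
(0.35 for species, 0.8 for genus, on a height-1 tree — chosen so a 60-tip
panel yields on the order of 30 species and 10 genera, the composition of a
realistic regional collection), which guarantees marker ⊆ species ⊆ genus
nesting.

`simulate_community_experiment()` emulates the consortium assay. The design
mirrors the assembly scheme: base communities of 3–6 members, each pool
strain added to each base (guaranteeing (B, B∪{i}) pairs for every strain),
topped up with random backgrounds to 176, under the similar-prevalence
constraint (relative spread of per-strain background counts ≤ 20%; small
toy designs can relax this via `max_spread`). Each background is assayed
alone and with each focal strain; monocultures and all pairwise co-cultures
complete the 606-assay bookkeeping, everything in triplicate.

The ground-truth landscape is generated bottom-up from per-strain FEE
parameters: F\*(∅) = 0 and
F\*(S) = clip(mean over i ∈ S of [(1+b_i)·F\*(S∖{i}) + a_i] + N(0, τ²)).
Averaging over all removal parents makes the truth permutation-symmetric by
construction. A consequence that matters for interpreting recovery tests:
the affine maps x ↦ (1+b_i)x + a_i commute only when a_i·b_j = a_j·b_i, so
no landscape can satisfy every FEE exactly, and the averaged landscape's
*descriptive* FEEs (what OLS on its ΔF-vs-F pairs estimates) are attenuated
relative to the generating (a_i, b_i) — each strain's direct term carries
weight 1/|S| in the average. Round-trip tests therefore compare fitted FEEs
with the noiseless landscape's descriptive regression (which they match
exactly at ε = 0), not with the generating parameters; and a "perfect
consumer" (a, b) = (0.95, −1) saturates a community only through its own
addition path, not through the average. Held-out prediction accuracy is
unaffected by this distinction, because predictor and landscape are
evaluated on the same descriptive scale.

Default parameter ranges span the qualitative strain classes seen in wine
consortia: intercepts a ∈ [−0.1, 1.0], slopes b ∈ [−1.2, 0.2] for pool
strains, focal fermenters at a ≈ 0.9 with b ≈ −0.95 (strong consumers
pushed off the perfect y = 1 − x line); residual scales σ ∈ [0.01, 0.1];
landscape noise τ = 0.01 and measurement noise ε = 0.01, both on the [0, 1]
function scale; 3 replicates. Clipping to [0, 1] is applied both during
generation and at measurement, keeping the fraction interpretation.

What the generator does *not* emulate: growth kinetics and OD curves, wine
chemistry (the physicochemical traits are statistically, not mechanistically,
generated), strain abundances, batch effects between experiments, and any
systematic (non-Gaussian) measurement error. Passing tests on these data
show the estimators are correct and well-calibrated under the stated
models; they do not certify the models themselves against real
fermentations.

## 5. Tunable parameters

| Parameter | Where | Default | Units / rationale |
|---|---|---|---|
| `tolerance` | `read_newick()` | 1e-6 | fraction of tree height; chronogram rounding slack |
| `n_perm` | `lambda_significance()` | 1000 | permutations; "significant" = p < 0.05 |
| `lambda` | `impute_tips()` | 1 | pure Brownian imputation; plug in λ̂ per trait if desired |
| `exclusion` | `loocv_impute()` | strain | strain / marker / species / genus radius |
| `sigma2_floor` | `fit_fee()` | 1e-4 | [0,1]² function scale; caps lattice edge weights |
| `scope` | `predict_function()` | interval | powerset for sensitivity analysis |
| `tau`, `eps` | generator | 0.01, 0.01 | landscape vs measurement noise sd |
| `max_spread` | generator | 0.2 | similar-prevalence constraint on backgrounds |

## 6. Test-suite problem sizes

The suite exercises the estimators at the scale of the study design it
emulates: 100-tip trees for λ recovery (50 replicates) and the permutation
test's type-I error (200 null runs at n_perm = 199); 60-strain collections
over 20 seeds for the exclusion-radius ordering; the full 176-background,
12-strain, triplicate design (with 131 held-out communities) for end-to-end
landscape accuracy, with the additive-degradation check repeated over 20
seeds. Oracle comparisons (brute-force multivariate-normal densities,
path-walking distances, message-passing imputation, generic numerical
minimisation of the lattice objective) run on 8–10-tip trees and ≤4-latent
lattices where exhaustive computation is exact. The whole suite runs in
about two and a half minutes on one CPU.

## 7. Known limitations

- λ is searched on [0, 1] only; some implementations allow λ slightly
  above 1 on trees whose structure permits it.
- Imputation is univariate per trait; correlated traits are not pooled.
- The Mantel and naive p-values for the distance correlation answer
  slightly different questions (pair non-independence); both are reported,
  neither is privileged.
- FEE fits are OLS on replicate means; replicate-level weighting and
  errors-in-variables in F(B) are not modelled.
- The lattice predictor assumes Gaussian, independent FEE residuals with
  per-strain variance; correlated residuals across edges sharing a
  background are ignored.
- The prevalence-balancing sampler is stochastic; pathological small
  designs can be infeasible at the default 20% spread and must relax
  `max_spread`.
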