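---
title: "Testing implicational universals with spatiophylogenetic controls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing implicational universals with spatiophylogenetic controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glottocoevo)
```

## The problem

An implicational universal is a cross-linguistic claim of the form *"if a
language has X, then it has Y"* — for instance, "if nouns precede numerals,
nouns precede adjectives". Counting how many languages obey such a claim is
misleading: languages are related by descent and influence one another
through contact, so a sample of 2,000 languages contains far fewer
independent data points than 2,000. `glottocoevo` implements a three-stage
testing pipeline that addresses this head-on:

1. **Naive stage.** A Bayesian logistic regression of the condition part of
   the universal on the result part, ignoring relatedness. This stage
   exists mainly to show how much apparent support evaporates once controls
   are added.
2. **Spatiophylogenetic stage.** The same regression with random effects
   capturing shared ancestry (a phylogenetic covariance from a posterior
   sample of trees), spatial proximity (an exponential kernel on
   great-circle distance), and macro-area membership. Refit on each tree of
   the sample; support requires the medians of the per-tree 95% CI bounds
   of the fixed effect to fall on the same side of zero.
3. **Co-evolution stage** (only for universals the second stage supports).
   Dependent and independent continuous-time Markov models of the paired
   binary traits are compared by stepping-stone marginal likelihoods on
   each tree; support requires the lower bound of the 95% HDI of the
   per-tree log Bayes factors to exceed 10 — deliberately conservative
   given the many universals tested in a battery.

A universal counts as supported overall only if stages 2 **and** 3 agree.
Follow-on analyses quantify *how* supported universals evolve: whether
transition rates into the harmonic state (both features present) exceed the
rates out of it, and what the most probable ancestral states were.

## The co-evolution model

The trait pair is recoded as a four-state variable: 1 = (0,0), 2 = (0,1),
3 = (1,0), 4 = (1,1) (letters A–D in the ancestral-state machinery). The
**dependent** model has eight transition rates
\(q_{12}, q_{13}, q_{21}, q_{24}, q_{31}, q_{34}, q_{42}, q_{43}\); dual
transitions (1↔4, 2↔3), which would require both traits to change at the
same instant, are structurally forbidden. The **independent** model
constrains each trait's gain/loss rates to ignore the other trait's state:
\(q_{13}=q_{24}=\alpha_1\), \(q_{31}=q_{42}=\beta_1\),
\(q_{12}=q_{34}=\alpha_2\), \(q_{21}=q_{43}=\beta_2\). Because the
independent model is implemented by mapping onto the dependent
parameterization, its likelihood is *exactly* nested (a property the test
suite asserts at 1e-12).

Likelihoods are computed with Felsenstein's pruning algorithm (C++, with
per-node rescaling so trees with thousands of tips do not underflow).
Transition matrices come from an eigendecomposition of the generator —
\(P(t) = U e^{\Lambda t} U^{-1}\) — with a complex-arithmetic path for
generators with complex spectra and a scaling-and-squaring fallback when
the decomposition is ill-conditioned (reconstruction error above 1e-9).
Tips with one missing trait get ambiguity vectors (two 1s) rather than
being dropped, although the compilation step's listwise deletion means this
path is mostly exercised by reuse.

Rates carry a gamma prior whose mean and variance are themselves uniform on
(0, 10] and are resampled as part of the chain, so the data choose the rate
scale. The root is treated as uniform over the four states in the
co-evolution analyses (the conventional default for this model family);
FitzJohn weighting is used in the ancestral-state module and is available
everywhere as an option.

### MCMC and marginal likelihoods

`sample_posterior()` runs a component-wise Gaussian random walk on log
rates (one component per iteration, round robin) with Robbins–Monro
adaptation toward 30% acceptance during burn-in only, plus reflective
uniform moves for the two hyperparameters. A tree sample is handled by
cycling: the chain spends `trees_per_block` consecutive iterations on each
tree, so retained samples integrate over phylogenetic uncertainty.

`stepping_stone()` estimates log marginal likelihoods along a ladder of
power posteriors with Beta-quantile spacing \(\beta_k = (k/K)^{1/0.3}\)
(dense near the prior, where the integrand changes fastest), warm-starting
each stone from the last and accumulating
\(\sum_k \log \tfrac1n \sum_i e^{(\beta_k - \beta_{k-1})\,\ell_i}\) in
log-sum-exp form. Each recorded sample is a full sweep over components;
this matters — with single-component recording the estimator's run-to-run
spread on a 300-tip dataset was several log units, with sweeps it is well
under one. Two structural identities pin the estimator down: a flat
likelihood gives log Z = 0 for any ladder, and on a conjugate
Bernoulli–Beta toy it must match the closed-form marginal within 0.05.

Bayes factors are reported as natural-log differences, dependent minus
independent; the per-tree mode (one log Z pair per tree, HDI over the
resulting BFs) is the default. Studies in this tradition summarize a
"median BF and its 95% HDI" over a tree sample, which the per-tree mode
matches most directly; a within-chain tree-cycling alternative exists, and
the output records which mode produced each summary.

## The spatiophylogenetic GLMM

For taxa \(i\): \(\mathrm{logit}\,P(y_i = 1) = a + b\,x_i + u^{p}_i +
u^{s}_i + u^{m}_{\text{area}(i)}\) with \(u^p \sim N(0, \sigma_p^2
C_{\text{phylo}})\), \(u^s \sim N(0, \sigma_s^2 C_{\text{spatial}})\) and
iid macro-area intercepts. The response is the **condition** part of the
universal and the fixed effect the **result** part. Covariance matrices
are standardized by their maximum diagonal entry so variance components
are comparable across trees of differing depth; the choice is recorded in
run metadata. The
spatial kernel is exponential decay on haversine distance with a 1,000 km
length scale — roughly the range at which sustained contact between speech
communities is plausible; both kernel and scale are configurable and
logged.

The sampler whitens each latent field through a Cholesky factor of its
covariance and updates it by elliptical slice sampling (tuning-free and
always-accepting, the standard choice for Gaussian-process-type latents),
with adaptive random-walk MH for \((a, b)\) and the log SDs. Priors are
Normal(0, 5²) on intercept and slope and half-Normal(0, 2²) on SDs —
weakly-informative defaults in the style of mainstream Bayesian regression
packages. Setting all SDs to zero recovers the naive model
(asserted in the tests as a nesting check).

The family-control variant replaces the covariance structure with random
intercepts and slopes by language family (independent scales, no
intercept–slope correlation) and retains only families with at least five
members; the number of taxa and families dropped by that filter is part of
the result object.

**Support rules.** Naive: the single 95% CI excludes zero. Over trees: the
median of lower bounds and the median of upper bounds are on the same side
of zero — "median of the 95% CI" is read as median-of-bounds rather than
median-of-per-tree-decisions, and the output flags the rule used. Boundary
ties (a bound exactly at zero, an HDI lower bound exactly at 10) count as
*no* support.

## Ancestral states

The four-state variable is fitted with an all-rates-different Markov model:
all 12 ordered-pair rates free, including the dual transitions the
co-evolution model forbids. One rate class only: the hidden-rates model
family is restricted to its single-category case, which is the plain
Mk/ARD model; the restriction is deliberate and documented.
Optimization runs on log rates in [1e-9, 100] from five Gamma(1,1) random
starts. The likelihood uses FitzJohn root probabilities (each state
weighted by its own normalized root partial) and the Lewis correction for
the ascertainment bias of analysing only variable characters,
\(L_{\text{corr}} = L / (1 - \sum_s L_s)\) with \(L_s\) the likelihood of
all tips fixed in state \(s\). The correction is constant in the node
states, so it cancels from marginal reconstructions; it matters for the
fitted rates. Marginals combine the rescaled down-pass with an up-pass that
forms sibling products explicitly (no divisions, safe with zero
probabilities) and are exact given the MLE rates — the tests compare them
against brute-force enumeration over all internal assignments.

## Harmonic versus disharmonic rates

From a dependent-model posterior, each retained draw yields indicators
\(q_{34} > q_{43}\) and \(q_{24} > q_{42}\) — transitions *into* the
harmonic state (1,1) against their reverses. Exact ties count as failures
of the inequality. Proportions are reported per pair and pooled; the
pooled proportion per universal enters a two-sided Wilcoxon signed-rank
test against 0.5. The test uses average ranks for tied magnitudes and an
exact null distribution computed by convolution over the (doubled) ranks up
to n = 25 — unlike the textbook tables this remains exact under ties — and
a normal approximation with continuity and tie corrections beyond.

## The synthetic-data generator

Real inputs for this kind of study are a global posterior tree sample, a
large typological database and geographic metadata. The generator replaces
them with:

* **Trees:** pure-birth (Yule) trees — adequate for exercising the
  analyses, though real language phylogenies are shaped by extinction and
  sampling — rescaled to height 1 by default. On that scale a rate of 1
  means one expected transition per root-to-tip lineage, so the battery's
  rates of 0.2–5 span feature stability from nearly frozen to fast-cycling,
  and a 300-tip tree accumulates a few dozen changes per trait: the same
  order of magnitude one would expect of a structural feature on a global
  language tree.
* **Tree uncertainty:** lognormal multiplicative jitter (sdlog 0.1) on
  branch lengths, topology held fixed. This emulates the variance of a
  posterior sample cheaply; it does not emulate topological uncertainty.
* **Geography:** Brownian diffusion of longitude/latitude along the tree
  (default 200 deg²/unit), longitude wrapped, latitude clipped; macro-areas
  by k-means on tip locations; families as the clades whose stem crosses a
  configurable age threshold (default a third of the height).
* **Traits:** either CTMC pairs simulated by Gillespie's algorithm under a
  dependent or independent generator — rooted by default in the both-absent
  state, matching the natural history of an implicational universal
  (features arise and then co-evolve) and keeping tip occupancy away from
  the degenerate all-harmonic corner — or regression-style pairs with a
  known fixed effect and phylogenetic/spatial random fields, used for
  effect-recovery and confounding experiments. Null calibrations of the
  rate analysis instead draw the root from the stationary distribution.
* **Missingness:** completely at random. Real typological missingness is
  feature-structured, but since compilation performs listwise deletion per
  universal, MCAR suffices to exercise the machinery.

Every generated dataset ships with a truth record, so pipeline output can
be scored against the generating parameters (closed-loop testing).

What passing tests on these data do **not** show: robustness to tree
misspecification, to contact-driven trait borrowing (which violates both
the CTMC and the GLMM), to feature-structured missingness, or to the
binarization choices a real database requires.

## Numerical and scale choices

* Matrix exponentials: eigendecomposition with spectral projectors (real
  fast path), complex path for complex spectra, `expmat`/`Matrix::expm`
  fallback; accepted only if the decomposition reconstructs Q to 1e-9.
* HDIs: shortest contiguous window over sorted samples, ties broken toward
  the earliest window.
* PSD repair: covariances whose smallest eigenvalue dips below −1e-8 are
  rebuilt with negative eigenvalues clipped; Cholesky factors get a 1e-8
  diagonal jitter.
* Master seeds are split into per-universal, per-stage seeds by hashing
  the universal id and stage label, so battery results are reproducible
  and independent of execution order.
* Desk-scale defaults (used by the analysis scripts and tests): 300-tip
  trees, 5–10 trees per sample, GLMM chains of a few thousand sweeps,
  stepping-stone ladders of 6–10 stones with ~100–150 recorded sweeps per
  stone, rate chains of 15,000–200,000 single-component iterations. The
  `full` profile scales everything to the settings large cross-linguistic
  studies run on clusters (100 trees, tens of millions of iterations) and
  is not meant for a laptop.

## Known limitations

* The GLMM sampler is single-chain; convergence diagnostics beyond
  acceptance rates, ESS and a split-R̂ are out of scope.
* The co-evolution machinery covers exactly two binary traits; no hidden
  rate classes, covarion variants or reversible-jump averaging.
* Conjunction-only conditions: "X1 and X2 imply Y" is expressible,
  disjunction or negation beyond literal values is not.
* Stepping-stone estimates at desk scale carry Monte-Carlo error of order
  one log unit; decisions near the BF = 10 boundary deserve a rerun at a
  finer ladder.
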