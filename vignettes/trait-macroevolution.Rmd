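---
title: "Regime-painted trait macroevolution: models, tests, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regime-painted trait macroevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroevo)
```

This vignette is the package's account of its science: the unified model
behind the eleven trait-evolution scenarios, the statistics built on it,
the choices made where the design was genuinely open, and what the
synthetic-data generators do and do not establish.

## 1. One Gaussian process, eleven scenarios

All scenarios are special cases of a time-inhomogeneous Gaussian diffusion
on a *painted* ultrametric tree. A painting assigns to every branch an
ordered list of age segments, each carrying a discrete regime state; the
time slice, the habitat belts, the focal clade, and the biogeographic
regions are all just paintings. Within a segment in state $s$ the trait
follows

$$dX_t = \alpha_s(\theta_s - X_t)\,dt + \sigma_s(t)\,dW_t,$$

with $\alpha_s = 0$ for Brownian segments and
$\sigma^2(t) = \sigma_0^2 e^{rt}$ ($r \le 0$, $t$ measured from the root)
for the early-burst model. Writing $A_i(s,t) = \int \alpha$ along lineage
$i$, tip moments follow from per-segment closed forms propagated from the
root:

* mean: $m \leftarrow m e^{-\alpha\Delta} + \theta(1 - e^{-\alpha\Delta})$;
* lineage variance: $V \leftarrow V e^{-2\alpha\Delta} +
  \frac{\sigma^2}{2\alpha}(1 - e^{-2\alpha\Delta})$ (limit
  $\sigma^2\Delta$ as $\alpha \to 0$; $\sigma_0^2(e^{rb}-e^{ra})/r$ for
  EB segments);
* covariance: $\mathrm{cov}(i,j) = V(t_m)\,
  e^{-A_i(t_m,T)}e^{-A_j(t_m,T)}$ at the MRCA time $t_m$.

`trait_moments()` implements this generic recursion; the fitting path uses
algebraically equivalent closed forms per family (regime-occupancy shared
times for multi-rate BM, depth-matrix formulas for OU and EB), and the two
routes are cross-checked against each other and against 200,000-replicate
branchwise simulations in the test suite. `1 - e^{-x}` terms use `expm1`
so that the $\alpha \to 0$ Brownian limit holds to near machine precision.

### Parameter counts and root conventions

The source analysis does not state parameter counts; the package uses the
minimal standard parameterizations: BM1 $k=2$ ($x_0, \sigma^2$); OU1 $k=3$
($\theta, \alpha, \sigma^2$, root fixed at $\theta$); EB $k=3$; SHIFT
$k=3$; ER $k=3$ with $\sigma^2$ shared across the slice (a
release-and-radiate variant with a free post-slice rate, $k=4$, is
available via `er_release = TRUE`); BMM $k=3/4$ for 2/3 regimes; OUM
$k=4/5$. The OU root is fixed at the root-regime optimum by default, with
a `"stationary"` option; one convention must be used across a comparison
table, and `compare_scenarios()` takes it once in its options.

Whether the original fits used fixed or stationary roots is not stated;
fixed-at-optimum is the default here because it is the parameterization
under which OU1 nests cleanly inside OUM (equal optima collapse the
likelihoods exactly, which the tests assert).

### The branch-state convention

Node-state reconstructions must be turned into branch paintings. A branch
takes the ML state of its *child* node (stem-of-clade convention), so a
clade's stem branch carries its MRCA's state — this matches painting a
focal clade from its MRCA downward. The alternative (parent-node states)
would leave a reconstructed regime's stem in the background state. The
convention is a documented choice; the source only shows painted figures.

### Fitting

Linear mean parameters ($x_0$ or the $\theta_s$) are profiled by GLS and
the global $\sigma^2$ scale has a closed-form ML profile, leaving at most
two "shape" parameters per scenario ($\log\alpha$, $r$, or log rate
ratios). One-dimensional shapes are optimized by a deterministic 15-point
grid scan plus Brent refinement — in 1-D this dominates seeded
Nelder-Mead restarts in both robustness and cost, and makes fits exactly
reproducible; the two-ratio BMM_Geo shape keeps Nelder-Mead from 5 seeded
starts. EB's exponent is bounded in $[-10/T, 0]$ and the bound values are
evaluated explicitly so that a boundary optimum is returned exactly
($\hat r = 0$ on Brownian data). The covariance gets a
$10^{-10}\,\mathrm{tr}(V)/n$ diagonal jitter before Cholesky
factorization; failure beyond jitter is a hard error, and degenerate
inputs (constant traits) return boundary fits flagged by `converged`.

## 2. Mk ancestral states and regime painting

Habitat (2-state) and region (3-state) regimes are painted from marginal
ancestral-state reconstructions under a symmetric-Q Mk model. The marginal
at a node is computed by a down (pruning) pass and an up (outside-subtree)
pass; with a symmetric Q and uniform root prior this equals the re-rooting
method and exhaustive enumeration over joint histories, which the tests
verify to $10^{-8}$ on 100 random small trees. The root prior is uniform
(the source is silent; for symmetric Q the stationary prior coincides).
Three-state data use SYM (3 free rates) with an ER fallback, logged, when
any state has fewer than 3 tips. Exact ties in ML states resolve toward
the parent's state, root-down. No ambiguity threshold is applied — raw
marginals are always reported alongside.

## 3. Disparity through time and MDI

Disparity of a set of tip values is the average squared pairwise distance
(equal to twice the sample variance); relative disparity at an
internal-node time is the mean over all lineages alive at that instant of
subclade disparity over whole-clade disparity. The curve starts at 1 at
the root by normalization and is invariant to affine trait
transformations. MDI integrates (trapezoid, curve extended flat to
relative time 1) the difference between the observed curve and the
pointwise median of Brownian simulations whose rate is the ML estimate
from the data; per-simulation MDIs against the same median give the
simulation p-values. Both tails are reported: the source's printed p
behaves like $\Pr(\mathrm{MDI}_{sim} \le \mathrm{MDI}_{obs})$ (a positive
MDI was called significant at $p = 0.98$), so `p_le` is labelled the
"paper convention", but the choice of tail is genuinely unstated and
`p_ge` is always present.

## 4. The parametric-bootstrap (pmc) power test

Two fitted scenarios give $\delta_0 = 2(\ln L_2 - \ln L_1)$ (model 1 =
poorer AICc). Datasets are simulated under each fitted model; each is
refit under both models. $p$ is the fraction of the model-1 (null) deltas
at or above $\delta_0$; power is the fraction of model-2 deltas at or
above the null's 95th percentile. Bootstrap refits use fresh stochastic
grid starts so that the delta distribution is continuous even when the two
models are equivalent — with a fully deterministic optimizer,
self-comparison would produce exact ties and a degenerate power of 1; with
fresh starts it calibrates to 0.05 by construction, which the acceptance
suite checks at nsim = 500. Negative deltas (optimizer noise on nested
models) are kept, never clamped. Paintings are inherited from the original
tree inside the bootstrap — the source simulates on the fixed MCC tree
with fixed mappings, and re-running ancestral-state estimation per
replicate is deliberately out of scope.

## 5. The preparation chain

Species means are log range midpoints, $(\log\min + \log\max)/2$.
Missing cells are imputed on the hybrid matrix of log ranges plus the
first ten phylogenetic eigenvectors (principal coordinates of the
patristic distance matrix via Gower double-centering of $-D^2/2$; the
count 10 is a knob mirroring the original setting, no selection rule is
applied). The imputer sweeps incomplete columns in increasing-missingness
order, refitting a regressor per column until the summed squared change
first increases or 20 iterations pass. Two regressors are provided: a
bagged regression-tree ensemble (random-forest style, `ntree`
configurable, out-of-bag NRMSE — the environment provides no random-forest
package, so the ensemble is implemented in-package) and a deterministic
ridge (2-fold cross-fitted NRMSE) that is the default and the test-suite
regressor. NRMSE is held-out (out-of-bag / cross-fitted), resolving the
unstated train-vs-OOB question in favor of the honest estimate. Imputed
min/max pairs can invert; the pipeline reorders them, which leaves the
midpoint unchanged. Observed cells are never altered, asserted
cell-by-cell.

Size correction regresses each shape trait on plant size by GLS under the
shared-time covariance and keeps raw residuals. Phylogenetic PCA uses GLS
means and the evolutionary covariance
$R = (X-\bar a)^\top C^{-1} (X-\bar a)/(n-1)$ — covariance mode for
morphology (common log-mm scale), correlation mode for the 22
heterogeneous climate variables. Loadings are evolutionary correlations
between traits and scores; each axis is flipped so its largest loading is
negative, a cosmetic convention easing comparison with published tables.
Independent contrasts use the standard recursion (polytomies resolved with
zero-length branches, logged) and the correlation test runs through the
origin with $n-2$ df.

## 6. What the synthetic data emulate — and what a green test shows

The study's raw data were never deposited, so the generators *are* the
test substrate. They reproduce the study's shapes: a 63-tip, 7.16-Myr
pure-birth tree; a posterior sample emulated by lognormal node-age jitter
(taxa and topology fixed, root height preserved — matching how analyses
were repeated over 100 posterior trees); Mk-evolved habitat and 3-state
region histories; six morphological traits built from a plant-size
backbone (three-rate geographic BM) with clade-shifted leaf optima and
clade-specific flower rates; SLA and an altitude factor with
habitat-specific optima; min/max range tables with 6% missing cells; and
a climate matrix driven by an altitude factor (ALT negative, temperature
and precipitation variables positive) and a latitude factor (LAT positive,
LONG negative, seasonality negative) whose phylogenetic PCA recovers the
planted sign pattern. Variable-specific climate residuals are Brownian on
the tree rather than iid — a phylogenetic ordination GLS-weights
observations by $C^{-1}$, which would amplify iid noise through short
terminal branches and drown the factors; real climate residuals are
themselves phylogenetically structured.

A green suite therefore establishes that the *methods* are correct
(moments match exact simulation; marginals match enumeration; estimators
are calibrated and recover planted parameters at realistic sizes), not
that the original study's printed numbers are reproduced — those depend on
data that cannot be obtained. Reported magnitudes (e.g. an imputation
NRMSE near 0.6 on synthetic ranges vs the original 0.042) reflect the
synthetic world's weaker between-species spread, and are not comparison
targets. Likewise, eigenvector augmentation is only expected not to hurt
imputation when traits carry phylogenetic signal that their covariates do
not already contain; with near-duplicate columns (a min/max pair predicts
itself) the phylogeny adds nothing, and the paired-seed test world uses
mildly correlated, strongly phylogenetic traits for exactly this reason.

## 7. Numerical choices and known limitations

* Ultrametry is enforced at relative tolerance $10^{-6}$; ages are Myr
  before present, tips at age 0.
* Polytomies are accepted by all covariance-based machinery; only PIC
  resolves them (zero-length, logged).
* ΔAICc ties break by the fixed scenario order of the comparison table.
* The package is univariate per trait (each PCA axis analyzed separately,
  as in the source); correlated multi-trait fitting, Bayesian estimation,
  non-ultrametric/fossil trees, and stochastic character mapping are out
  of scope.
* Grid bounds: $\alpha T \in [10^{-6}, 500]$, log rate ratios in
  $[-10, 10]$, $r \in [-10/T, 0]$. Estimates at these bounds are returned
  (flagged via `converged`/boundary values), not hidden.
* `simulate_posterior_sample` jitters ages with bounded retries and a
  deterministic fallback, so pathological jitter SDs cannot deadlock; the
  root age never moves.
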