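---
title: "medwgcna: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medwgcna: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medwgcna)
```

This vignette documents the statistical machinery behind `medwgcna`:
the network and differential models, the two-direction mediation screen
that is the package's core contribution, the permutation annotation
test, and the design decisions baked into the synthetic generators and
bootstrap. It is written for readers who want to know *what is actually
fitted*, not just which function to call.

## 1. Co-expression modules

For a features × samples matrix $X$, the adjacency between features
$i,j$ is the soft-thresholded correlation
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ (unsigned; the signed variant
uses $((1+\mathrm{cor})/2)^\beta$). `pickSoftPower()` selects the
smallest power whose connectivity distribution fits a scale-free law
(binned log–log regression $R^2 \ge$ `r2Cut`), warning and falling back
to the best-fitting candidate otherwise.

The topological overlap between features is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}},$$

with unit diagonal; `detectModules()` cuts average-linkage
hierarchical clustering of the dissimilarity $1 - \mathrm{TOM}$ at a
fixed height (default: midpoint of the largest merge-height gap) and
discards clusters below `minSize`. Module labels are canonical —
ordered by decreasing size, ties broken by the lexicographically
smallest member — so results do not depend on input feature order.

A module eigengene is the first right singular vector of the
row-standardized module submatrix, scaled to unit standard deviation
and sign-aligned so that the average module feature correlates
positively with it.

```{r modules}
sim <- simulateModularExpression(120, data.frame(size = c(40, 30),
                                                 rho = c(0.8, 0.8)),
                                 nBackground = 60, seed = 1)
mods <- buildModules(sim$matrix, power = 6, minSize = 20)
mods
```

## 2. Differential testing

Module eigengenes and within-module features are tested with an
empirical-Bayes moderated t-statistic. Per-unit residual variances
$s_g^2$ from a common design matrix are shrunk toward a pooled prior
$s_0^2$ with prior degrees of freedom $d_0$, both estimated by the
standard moment-matching of a scaled inverse-chi-squared model on
$\log s_g^2$; the moderated statistic has $d_g + d_0$ degrees of
freedom. `priorDf = 0` recovers the ordinary t-test and
`priorDf = Inf` the pooled-variance limit; the unit tests verify both
limits and agreement with `limma::eBayes` on shared data.
`type3AnovaScreen()` offers a marginal (type-III) ANOVA screen for
designs with several crossed covariates and errors on aliased
(rank-deficient) designs instead of silently dropping terms.

## 3. The causal screen

Let $E$ be a module eigengene, $M$ a differential feature of the
module, $Y$ the phenotype and $C$ observed confounders. For each
feature two mediation models are fitted by the product method:

- **forward** (driver): exposure $E$, mediator $M$, outcome $Y$. The
  $a$-path regresses $M$ on $E$; the $b$-path regresses $Y$ on $M$
  adjusting for $E$. The indirect effect is $ab$.
- **reverse** (passenger): exposure $Y$, mediator $M$, outcome $E$.

To avoid the mediator tautologically containing itself in the
exposure, the forward direction uses a leave-one-out eigengene: the
module eigengene recomputed without the feature under test.

Binary variables are fitted by logistic regression (an internal
iteratively reweighted least-squares implementation that matches
`glm.fit` to numerical precision), continuous ones by least squares.
Confounding is handled by stabilized inverse-probability weights: the
exposure model $P(E \mid C)$ yields weights
$w = P(E)/P(E \mid C)$ (densities for continuous exposures), truncated
at the 1st/99th percentiles, and both paths are fitted weighted.

Inference on $ab$ uses a percentile bootstrap: $p$ is the smallest
two-sided level at which the percentile interval excludes zero, with
the usual $+1$ correction, so $p \ge 2/(B+1)$. The screen applies
Benjamini–Hochberg correction *per direction* and labels each feature

- `driver` — forward significant, reverse not;
- `passenger` — reverse significant, forward not;
- `ambiguous` — both; `none` — neither.

### Bootstrap resolution and the p-value floor

With $B$ bootstrap draws no p-value can fall below $2/(B+1)$. Under BH
across a few dozen features, a single true positive sitting at the
floor may be undetectable, and a false positive censored *at* the floor
can look maximally significant. `causalScreen()` therefore supports a
two-stage scheme: all features are screened at `nBoot`, then
candidates whose stage-1 p-value is small (`p <= refineCut`) but whose
BH-adjusted value is not already decisive are re-bootstrapped at
`refineBoot` draws with a deterministic per-feature seed. This spends
computation only where resolution matters and leaves the procedure
fully reproducible.

```{r screen}
simM <- simulateMediationScenario(nSamples = 200, seed = 3)
ms   <- computeEigengenes(simM$matrix, simM$moduleLabels)
dft  <- diffFeaturesWithinModule(simM$matrix, ms, "ME1",
                                 simM$phenotypes)
scr  <- causalScreen(simM$matrix, ms, dft, "ME1", simM$phenotypes,
                     nBoot = 200, seed = 3)
table(scr$label[!duplicated(scr$feature)])
```

## 4. Topology-aware annotation

`buildEdgeTermMap()` lists a module's internal edges (canonical
feature pairs with TOM or adjacency weights) and maps each gene-set
term to the edges whose *both* endpoints belong to the term. The term
score is the summed weight of its edges. `edgeShuffleTest()` permutes
the weights over the module's edges, preserving the term's edge count
and the weight multiset, and reports the one-sided permutation p-value
$(1 + \#\{\text{shuffled} \ge \text{observed}\})/(B+1)$. A term
covering every edge is permutation-invariant and correctly gets
$p = 1$. `edgeHypergeomTest()` and `geneHypergeomEnrich()` provide the
classical overlap tests for comparison.

## 5. Multi-omics clustering and imbalance-aware classification

`multiccaMerge()` merges omics layers by iterated pairwise canonical
correlation analysis. Each block is first whitened through a truncated
PCA basis (rank = `nCC`); without the truncation, any block with more
features than samples yields canonical correlations of exactly 1 and a
meaningless merge. `wgcnaMerge()` instead concatenates per-omic module
eigengenes. `clusterSelectK()` runs k-means over candidate $k$ and
picks the silhouette-optimal value, reporting Calinski–Harabasz and
Davies–Bouldin indices alongside.

`trainEnsemble()` addresses class imbalance with bagging-SMOTE
(mode 1): ten base training sets, each brought to exact class balance
by bootstrapping the majority class and topping up minority classes
with SMOTE-interpolated synthetics; mode 2 is plain bagging and mode 3
a single learner on the raw data. Features are pre-screened by ANOVA
and filtered by recurrence of nonzero elastic-net coefficients across
base sets; base learners (SVM or multinomial logistic regression) vote
by averaged class probabilities.

## 6. Design of the synthetic generators

`simulateMediationScenario()` plants a ground-truth causal structure
used throughout the validation suite:

- a latent module factor $f_0$ and latent driver signals $d_0$;
- a binary phenotype whose log-odds contain the *driver signal* and
  the *module factor* plus a confounder, with the intercept solved
  numerically for a target prevalence;
- the driver feature loads weakly on the module and strongly on $d_0$;
- passenger features load strongly on the module **and additionally on
  the realized phenotype**, which makes them consequences of the
  outcome;
- null module features load moderately on the module only.

Two identifiability choices matter. First, the driver's module loading
sits at the point where the reverse-direction collider path through
the eigengene cancels, so a true driver is not mislabelled
`ambiguous`. Second, the passengers' phenotype shift is a *shared*
component: it is absorbed by the module eigengene, so conditioning on
the (leave-one-out) eigengene removes it from the forward $b$-path and
passengers are not mislabelled drivers. These are properties of the
generative design, fixed before the validation suite was run, not
knobs tuned to it.

## 7. Determinism

Every stochastic routine takes an explicit seed and restores the
caller's RNG state; bootstrap and permutation draws use
deterministically derived per-feature seeds. The pipeline writes every
artifact with fixed numeric formatting and records MD5 checksums in
`manifest.json`; two runs with the same configuration are
byte-identical (the wall-clock log aside).

## 8. Limitations

- The product-method indirect effect assumes linear (or logistic)
  structural equations and no unmeasured exposure–mediator or
  mediator–outcome confounding; IPW only corrects for *measured*
  confounders of the exposure.
- The percentile bootstrap is approximate for very small samples; the
  suite calibrates it at $n = 300$.
- The driver/passenger dichotomy is a screen, not a full causal
  discovery procedure: features with genuinely bidirectional roles are
  reported `ambiguous` and deserve targeted follow-up.
- Edge-shuffle annotation conditions on the observed weight multiset
  and term sizes; very small modules (few edges) have coarse p-value
  grids.
- Modules are detected from marginal correlations; a driver with weak
  co-expression (by design, the hard case) may not be assigned to the
  module by clustering alone and may need a prior-knowledge
  assignment, as in the example above.
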