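---
title: "Detecting and measuring phenotypic convergence with ouconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring phenotypic convergence with ouconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ouconv)
```

# The problem

Repeated, independent evolution of similar phenotypes — convergence — is a
central line of evidence for adaptation. A typical study system is a clade
of lizards in which a handful of distantly related desert species share a
distinctive head shape: one very old lineage (diverging from the rest on
the order of 77 My ago) and several members of a much younger radiation
(~12 My deep). `ouconv` implements the full analysis chain such a study
needs, from 2-D landmark data to formal convergence statistics:

1. **Shape quantification**: generalized Procrustes superimposition (GPA) of
   10-landmark configurations, covariance PCA of aligned coordinates, and
   per-species mean PC scores (`gpa()`, `pca_shapes()`,
   `species_mean_scores()`).
2. **Ancestral states**: branch-length-weighted squared-change parsimony,
   the Brownian-motion ML interior reconstruction
   (`squared_change_parsimony()`), and phylomorphospace layouts.
3. **Adaptive-regime detection**: a stepwise forward/backward search over
   multi-regime Hansen (Ornstein–Uhlenbeck) models compared by AICc
   (`surface_search()`), in the style of the SURFACE method.
4. **Convergence measures**: the distance-based C1–C4 and frequency-based
   C5 statistics with Brownian-motion simulation nulls
   (`group_c_metrics()`, `c_significance()`, `c5()`).
5. **Strength of convergence**: a Wheatsheaf-style index with bootstrap
   confidence interval and randomization p-value (`wheatsheaf_test()`).
6. **Synthetic data**: Yule trees and exact OU/BM trait simulation so that
   every stage is testable without any external download
   (`make_convergence_scenario()` and friends).

# Models and conventions

## Hansen (multi-regime OU) model

Each branch carries a selective regime; a *painting* assigns regime ids to
every branch (the entry for a node is the regime of the branch above it,
and the root entry names the root regime). Per trait, evolution follows
$dX = \alpha(\theta_{r(t)} - X)\,dt + \sigma\,dW$ with attraction $\alpha$
(1/My), diffusion $\sigma^2$ (trait²/My) and one optimum $\theta_r$ per
regime. Conventions, chosen where the method's users have historically had
to choose too:

* **Root state** is fixed at the root regime's optimum (no extra parameter);
  this is the classic Hansen/SURFACE convention.
* **Tip expectation**: $E[y_i] = \sum_r W_{ir}\theta_r$ where $W$
  accumulates $e^{-\alpha(T-t_{\mathrm{end}})} - e^{-\alpha(T-t_{\mathrm{begin}})}$
  over the lineage's branch segments in regime $r$, plus $e^{-\alpha T}$
  credited to the root regime. Rows of $W$ sum to one for every $\alpha$.
* **Tip covariance**: $V_{ij} = \frac{\sigma^2}{2\alpha}
  e^{-\alpha d_{ij}}(1 - e^{-2\alpha t_{ij}})$, with $d_{ij}$ the patristic
  distance and $t_{ij}$ the shared (MRCA) depth; non-ultrametric inputs are
  allowed with a warning and use the exact per-tip depths.
* **Per-trait** $\alpha$ and $\sigma^2$ with a shared painting; the joint
  log-likelihood is the sum over traits. Parameter count $p = m(2 + k')$
  for $m$ traits and $k'$ distinct regimes (shift *locations* are not
  counted), and AICc uses $n = \text{tips} \times \text{traits}$.

## Fitting and the alpha profile

At fixed $\alpha$ the optima are generalized least squares and
$\hat\sigma^2$ follows from the GLS residuals, so the likelihood is
profiled over $\alpha$ only. `hansen_fit()` evaluates a 32-point
log-spaced grid on $[10^{-6}/T,\ 10^{3}/T]$ ($T$ = tree depth) and then
polishes by golden-section search inside the bracketing cell. Because the
covariance factorizations depend only on $\alpha$ (not on the painting),
`hansen_prep()` caches one Cholesky factor and whitened trait vector per
grid point; a candidate fit inside the stepwise search then costs one
triangular solve. During the search (`refine = FALSE`) all models are
compared on the same grid profile, which keeps the AICc comparisons
mutually consistent; the grid spacing (factor ~1.9 in $\alpha$) was checked
to move merge decisions by well under one AICc unit.

## The stepwise regime search

The forward phase starts from one regime and, at each step, tries starting
a new regime on every branch that is not already a shift point, accepting
the single best AICc improvement (ties break toward the smallest postorder
branch index); the root stem is not a candidate. The backward phase
repeatedly evaluates all unordered pairs of regimes merged into one and
accepts the best improvement until no merge helps. The acceptance threshold
is any AICc decrease (> 0), exposed as `min_improvement`.

Bookkeeping counts regime **origins**: $k$ is the root origin plus the
number of shifts (so a single-optimum model has $k = 1$ and Brownian motion
reports $k = 0$), $k'$ the number of distinct regimes; a regime reached by
two or more origins is *convergent*, $c$ counts origins into convergent
regimes, and $\Delta k = k - k'$ summarizes how much convergence collapsed
the model. The four-model comparison reports AICc for the collapsed
convergent model (OUc), the forward-phase painting (OUnc), the
single-optimum model (OU1) and Brownian motion (BM).

## Convergence measures

With ancestral states $a(\cdot)$ from weighted squared-change parsimony,
for a tip pair the measures are built from $D_{\mathrm{tip}}$ (phenotypic
distance between the tips) and $D_{\max}$ (the maximum distance between any
node on the two lineages descending from their MRCA):
$C1 = 1 - D_{\mathrm{tip}}/D_{\max}$, $C2 = D_{\max} - D_{\mathrm{tip}}$,
$C3$ divides $C2$ by the summed change along the two lineages, and $C4$ by
the total change in the clade under the MRCA. For a focal *set*, C1–C3 are
means over pairs, while the group C4 divides the *summed* pairwise C2 by
one whole-clade denominator (the per-pair convention would force
$C4 \le C3$, which contradicts the published orderings this pipeline is
designed to reproduce). Significance comes from simulating the fitted
Brownian generator (per-trait rates plus contrast cross-covariances,
root at the GLS estimate) on the fixed tree and recomputing the measures —
including re-reconstructing ancestors — for the same focal labels;
$p = \#\{\mathrm{sim} \ge \mathrm{obs}\}/n_{\mathrm{sim}}$, so exact zeros
are reportable. A conservative $(+1)/(+1)$ estimator is not the default
because published tables print plain proportions.

C5 takes the convex hull of the focal tips on two phylomorphospace axes
(PC1–PC2 by default) and counts root-to-tip lineages that *enter* the hull
from outside, walking each lineage's branch polyline through exact
segment–hull clipping (touching the boundary counts as inside, with a
tolerance of $10^{-9}$ of the hull extent). Degenerate (collinear) focal
sets get a thin buffered rectangle and a warning.

## Wheatsheaf index

The method's original publication is not restated in the source study, so
the formula here is a documented convention, isolated in one function each
so it can be swapped: traits are z-scored across all species; pairwise
Euclidean distances are penalized by phylogenetic closeness,
$d'_{ij} = d_{ij}(1 + s_{ij})$ with $s_{ij}$ the MRCA depth as a fraction
of the deepest tip; the index is
$w = \overline{d'}_{\mathrm{all\ pairs}} / \overline{d'}_{\mathrm{focal\ pairs}}$.
It exceeds 1 when focal species are mutually closer — after the penalty —
than species pairs at large, reduces to a plain distance ratio on a star
tree, and equals 1 exactly when the focal set is all species. The p-value
recomputes $w$ for random focal sets of the same size (without
replacement); the 95% CI bootstraps species with replacement within the
focal and non-focal strata, redrawing degenerate resamples.

# The synthetic world

`make_convergence_scenario()` states the world the package is tested
against: 57 species — a 56-tip Yule radiation 12 My deep grafted 65 My down
a stem, next to one old tip diverging 77 My ago — with 3 traits and 6 focal
taxa (the old lineage plus five radiation members chosen by greedy maximin
patristic spread). Focal terminal branches are painted with one shared
convergent regime; everything else keeps the base regime.

Defaults of the strong-signal preset, chosen once: $\alpha = 3$/My (OU
half-life 0.23 My, small against the 12 My radiation), $\sigma^2 = 0.02$
(stationary SD $\approx 0.058$, the scale of PC scores), optima separated
by 0.6 per trait ($\approx 10$ stationary SDs, comfortably beyond the
"at least 3" the design calls for). Focal candidates must carry a terminal
branch of at least 1 My (≥ ~4 OU half-lives): a "convergent lineage" that
spent essentially no time under the regime would not instantiate the stated
biology, and nothing could recover it. The weak preset ($\alpha = 0.3$,
separation ≈ 1 stationary SD) exists for power studies.

What the generator does *not* emulate: trait cross-correlations,
measurement error, fossil/extinct diversity, and cladogenetic (speciational)
change. A green test therefore certifies the estimators against the OU/BM
world they assume, not against every feature of real morphometric data.

# Numerical choices

* Newick parsing is strict: branch lengths mandatory on all non-root edges,
  unique non-empty tip labels, bifurcating root, `[...]` comments stripped;
  errors carry the character position.
* GPA: full Procrustes, unit centroid-size scaling per iteration, proper
  rotations only (no reflections), consensus tolerance $10^{-10}$, at most
  100 iterations. No tangent projection by default. PCA eigenvector signs
  are fixed so each component's largest-magnitude loading is positive.
* Squared-change parsimony solves the sparse Laplacian normal equations by
  Cholesky; the factor is cached per tree so simulation nulls re-reconstruct
  ancestors cheaply. Zero-length interior branches are replaced by
  $10^{-8} \times$ tree depth with a warning.
* Constant traits floor $\hat\sigma^2$ at $10^{-12}$ with a degeneracy
  warning; the Hansen GLS adds a $10^{-12}$-scaled ridge against
  rank-deficient weight columns.
* All stochastic entry points take a seed; identical seeds give bitwise
  identical results.

# Known limitations

* **The all-focal-in-one-regime event is statistically marginal by
  construction.** Each focal taxon's deviation from the shared optimum is
  an independent stationary draw, so collapsing the last focal singleton
  into the common regime is an AICc decision whose likelihood side is a
  $\chi^2_m$-like quantity against a penalty of $2m$ plus a small
  correction. The *best* split of six such draws into two clusters — which
  is what a stepwise search leaves behind — is the maximum over partitions
  and is frequently "significant" by AICc even when the single-regime model
  is true. In repeated runs of the strong preset the search therefore
  unites all six focal taxa in one regime in roughly a third of replicates,
  with the rest ending in two adaptive-peak clusters of focal taxa (the
  four-model AICc ordering OUc < OUnc < OU1 < BM is reproduced throughout).
  This ceiling is a property of AICc model selection on six stationary
  draws with three traits, not of the search: an exhaustive search over
  partitions faces the same comparison. The acceptance test states the
  stronger recovery bar and is left failing rather than weakened.
* C1 is not continuous under the Brownian null: random tip pairs often
  realize $D_{\max}$ themselves, putting an atom at $C1 = 0$ and hence an
  atom near 1 in the p-value. The simulation p-values are valid
  (sub-uniform) but not exactly uniform.
* The Wheatsheaf index has little power when the non-focal species are
  themselves phenotypically homogeneous (as in a strong-$\alpha$ OU world
  where every species sits near an optimum): random focal sets are then
  nearly as tight as the truly convergent one. This matches the
  non-significant Wheatsheaf p-values typically reported alongside strongly
  significant C-metrics.
* The C5 null (each Brownian simulation defines the hull from its own
  simulated focal tips) tends to produce *more* hull entries than the
  observed tight focal region, because a hull drawn in the middle of a
  Brownian cloud is crossed by many lineages. The observed count being the
  minimum possible (only focal lineages enter) therefore yields a large
  $p$ under the $\ge$ convention; C5's evidential content here is the
  count and the identity of the entering lineages, and the p-value is
  reported for completeness.
* The regime search refits every candidate from scratch and is exact for
  the stated conventions, but it is quadratic in regimes during merging and
  linear in branches per forward step; trees far beyond a few hundred tips
  will be slow.
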