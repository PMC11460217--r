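---
title: "Symptom co-severity networks and second-order patient clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom co-severity networks and second-order patient clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

# Overview

`symptomnet` analyzes a patient-by-symptom matrix of ordinal severities
(0 = symptom not reported, 1 = slight, ..., 4 = very severe, the scale of
the Memorial Symptom Assessment Scale) in two complementary directions:

1. **Symptom networks.** A regularized Gaussian graphical model (GGM) over
   the symptoms: edges are partial correlations between severities after
   conditioning on all other symptoms, estimated by the graphical lasso
   with EBIC model selection after a rank-based nonparanormal transform.
   Symptom clusters come from walktrap community detection; symptom
   importance from strength/closeness/betweenness centralities and their
   bridge variants; accuracy and stability from case resampling.
2. **Patient subgroups.** A second-order clustering: each patient is
   represented by the concordance matrix $XX^\top/100$ of their severity
   vector $X$, patients are compared by the Adjusted Rand Index (ARI)
   between these matrices, and the resulting similarity matrix is clustered
   with walktrap. Subgroup membership is then modelled by multinomial
   logistic regression on demographic/clinical covariates.

Because severity data of this kind are typically not shareable, the package
ships a synthetic-cohort generator whose planted structure makes every
stage testable against ground truth.

# The network model

## Nonparanormal transform

Severities are heavily tied, zero-inflated ordinal variables; per-column
Shapiro–Wilk statistics are reported (`shapiro_screen()`) but never gate
the pipeline — the transform is applied unconditionally. Each column is
mapped through its average ranks $r_i$ to $\Phi^{-1}(r_i/(n+1))$ and
rescaled to unit sample variance. Ties share the average rank; the result
depends on the data only through the within-column ordering, so any
strictly monotone per-column recoding leaves it unchanged (a property the
test-suite asserts). The $n+1$ rank denominator is the plain variant;
shrunken/Winsorized denominators differ only in the extreme tails at these
sample sizes.

## Graphical lasso and EBIC

With $S$ the sample correlation matrix of the transformed data, the
precision matrix estimate maximizes
$\log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}|$.
The penalty applies to off-diagonal entries only, so `glasso_fit(S, 0)`
equals `solve(S)` and an identity $S$ returns an identity $K$ at any
penalty. The solver is a block coordinate descent on the working
covariance (compiled code), converged when the mean absolute change of the
off-diagonal working covariance falls below `tol` (default `1e-6`) times
the mean absolute off-diagonal of $S$; off-diagonal zeros are exact
(soft-thresholding, not rounding).

`select_network()` fits a 100-point penalty grid, log-spaced from
$\lambda_{\max}$ (the largest absolute off-diagonal correlation — the
smallest penalty that empties the graph) down to $0.01\,\lambda_{\max}$,
warm-starting each fit from the previous one, and picks the model
minimizing
$\mathrm{EBIC} = -n(\log\det K - \operatorname{tr}(SK)) + |E|\log n +
4|E|\gamma\log p$, with $|E|$ the number of nonzero upper-triangle entries
and $\gamma = 0.5$ by default (the standard conservative choice; $\gamma =
0$ recovers BIC). Edges are reported as partial correlations
$\rho_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$. When the selected model has no
edges the empty network is returned with a warning rather than an error:
low-burden cohorts genuinely produce sparse, unstable models, and the
pipeline reports them as skipped instead of fabricating structure.
Patients with any missing severity are dropped listwise before estimation
and $n$ in the EBIC is the number of complete rows.

## Communities, centralities, bridges

Community detection is walktrap (igraph, 4-step random walks, the
modularity-maximizing cut of the merge dendrogram) on the graph whose edge
weights are absolute partial correlations; isolated nodes become singleton
communities. Centralities follow the conventions of the network
psychometrics software family: strength is the sum of absolute edge
weights; shortest-path lengths are $1/|w|$ (not $-\log|w|$), giving
closeness as the reciprocal of the total distance to the other nodes of the
same component and betweenness as the fractional count of shortest paths
through a node. On disconnected graphs, cross-component distances are
excluded from closeness (not treated as infinite) so that z-scores stay
finite; fully isolated nodes get closeness 0. Bridge variants restrict the
same three measures to cross-community structure; they require at least two
communities, and bridge strength can never exceed strength. Absolute
weights are used throughout; for networks whose selected edges are all
positive (the planted generators produce only nonnegative couplings) this
is equivalent to signed weights.

# Stability assessment

`assess_stability()` draws $B$ case resamples (rows with replacement at the
original $n$; subsampling without replacement at $0.9n$ is available behind
`replace = FALSE` since the resampling flavour is a design choice, not a
result), reruns the entire penalty-path/EBIC selection on each, and
reports:

- per-edge 95% percentile intervals; an edge is *significant* when its
  interval excludes zero and its full-data weight is nonzero;
- per-symptom same-cluster proportions: walktrap is rerun per resample and
  resample clusters are matched to the reference clusters greedily by
  maximal Jaccard overlap (largest overlap first, one-to-one, ties broken
  by cluster id for determinism — the matching rule is this package's own
  choice); a symptom scores 1 when its resample cluster maps to its
  reference cluster;
- the distribution of the number of clusters found (empty-network resamples
  count as 0 clusters), and per reference cluster the proportion of
  resamples reproducing it exactly as a set.

The default $B$ is 1000; the bundled analysis scripts use $B = 200$, which
resolves the stable/unstable distinction with Monte-Carlo half-widths of a
few percent while keeping a laptop-scale runtime.

# Second-order patient clustering

For a severity vector $X \in \{0,\dots,4\}^p$ the concordance matrix is
$XX^\top/100$, whose entries are the 17 possible severity products scaled
by $1/100$. The ARI "between two matrices" is interpreted discretely: the
upper triangle including the diagonal of each matrix labels the
$p(p+1)/2$ symptom-pair cells by its exact integer product, and the
standard pair-counting ARI is computed between the two labelings. This is
the implementable reading of a continuous-matrix ARI — severity products
take at most 17 distinct values, so the labels are exact — and it
generalizes the binary co-occurrence concordance-network approach; it is
flagged here as this package's interpretation rather than a claim about any
other implementation. Two conventions close the degenerate corner: when
both labelings are constant (e.g. two all-zero patients) the raw formula is
0/0 and the ARI is defined as 1 for identical labelings and 0 otherwise
(an asymptomatic patient and a uniformly very-severe patient are *not*
similar); and the $1/100$ scaling is irrelevant by construction, which the
tests assert by recomputing without it.

The $n \times n$ similarity matrix (compiled all-pairs computation,
$O(n^2p^2)$ with a small constant) is used as the weighted adjacency of a
complete graph after flooring negative ARIs at zero (walktrap requires
nonnegative weights; negative ARIs are chance-level dissimilarity and carry
no attachment information). Walktrap runs `runs = 11` times under permuted
node orderings — the merge procedure is deterministic given node order, so
order permutation is the natural randomization proxy — with final labels
from the first (identity-order) run and a consistency report of pairwise
ARIs between runs. Per-subgroup severity profiles are means with normal
95% intervals ($\pm 1.96\,s/\sqrt{n_g}$, undefined for singleton
subgroups). Per-subgroup networks are re-estimated only when the
EBIC-selected model has at least $p/2$ edges (configurable); sparser models
are reported as skipped with the reason, which is the expected outcome for
minimal-symptom-burden subgroups.

# Subgroup membership regression

`fit_multinomial()` delegates the maximum-likelihood softmax fit to
`nnet::multinom` (categorical covariates expanded against their reference
levels, complete cases only, `reltol = 1e-10`) and computes the inference
around it: Wald p-values from the observed information, Bonferroni
correction with multiplicity $m$ equal to the number of non-intercept
coefficient tests across all non-reference equations (the natural default;
configurable), odds ratios, AIC, Cragg–Uhler pseudo
$R^2 = \bigl(1 - (L_0/L_1)^{2/n}\bigr)/\bigl(1 - L_0^{2/n}\bigr)$ evaluated
on the log scale, and the likelihood-ratio $\chi^2$ against the
intercept-only model. Quasi-separation is flagged (|coefficient| > 15) by
covariate name; rank-deficient designs are rejected outright. The default
reference subgroup is the one most demographically similar to the whole
cohort: continuous covariates contribute $|\bar x_g - \bar x|/s$, and
categorical covariates the total variation distance between level
frequencies; the smallest sum wins, and an explicit `reference` argument
bypasses the criterion. Changing the reference reparameterizes the
coefficients but leaves fitted class probabilities unchanged up to the
optimizer's convergence floor (about $10^{-7}$ with the tightened
tolerances; the test-suite asserts this).

# The synthetic-cohort generator

Generation follows a Gaussian copula with thresholding, deliberately the
same nonparanormal model the estimator assumes, so parameter-recovery tests
are well-posed. `planted_precision()` builds a block-exchangeable latent
correlation matrix — `within_block_corr` inside each planted symptom block,
`between_block_corr` across blocks, independence for unassigned symptoms —
and returns its inverse; with uncoupled blocks the inversion is block-wise,
making between-block partial correlations exactly zero. Requests outside
the positive-definite region fail, naming the offending smallest
eigenvalue. An arbitrary latent correlation can be supplied instead (used,
for instance, to plant a hub symptom coupled to every other symptom, whose
top strength centrality the tests then verify).

Each patient draws a subgroup from the mixing proportions, then a latent
normal vector with the subgroup's mean-shift profile, cut at four
increasing thresholds into severities 0–4. The default thresholds
`c(0, 0.85, 1.5, 2.1)` give roughly 50% zeros and a realistic decaying
tail (about 30/13/5/2% across severities 1–4) for an unshifted symptom.

Covariates are drawn *conditionally on the subgroup* so that the declared
`covariate_effects` are exactly the population multinomial log-odds versus
subgroup 1: an age-like covariate is normal with mean shifted by
$\beta_{\text{age}}\sigma^2$ (identical variance across subgroups), a
treatment-like indicator is Bernoulli with log-odds shifted by
$\beta_{\text{treat}}$, and a diagnosis-like categorical has exponentially
tilted level probabilities. By Bayes' rule these conditional families give
membership log-odds that are linear in the covariates with precisely the
declared coefficients, so the regression module can be tested for coverage
against known truth (planted treatment log-odds 1.2, i.e. OR 3.32, is
recovered with nominal Wald coverage at $n = 2000$).

## Study conditions used by the tests and the acceptance script

- *Symptom-cluster recovery:* 3 blocks of 4 symptoms, $p = 12$,
  $n = 1000$, within-block 0.4, between 0 — walktrap recovers the blocks
  exactly in essentially all seeds, and every symptom keeps its cluster in
  ≥ 90% of 200 resamples.
- *Patient-subgroup recovery* (`subgroup_cohort_spec()`): 3 equal
  subgroups, $p = 20$, $n = 300$, each subgroup elevating its own
  5-symptom block by 3 latent SD over a raised-threshold baseline
  (`c(1.0, 1.6, 2.2, 2.8)`, ~84% zeros per background symptom). The
  disjoint-active-symptom regime is the one the concordance/ARI
  construction targets: patients from different subgroups share few active
  cells. With a uniformly active baseline the observed profiles are not
  disjoint and recovery degrades gracefully toward chance — passing tests
  under the planted regime therefore do not certify performance on cohorts
  whose subgroups differ only in degree, not in kind.
- *Regression recovery:* `default_cohort_spec()` at $n = 2000$, planted
  treatment log-odds 1.2 on subgroup 2 and age effects $\pm 0.02$.
- *End-to-end determinism:* the full pipeline at $n = 1000$, $p = 20$,
  $B = 200$ is byte-identical across reruns with the same seed; all
  randomness derives from a single root seed split per stage.

These sizes keep the complete test-suite and the acceptance script at a
few minutes on one CPU while leaving comfortable Monte-Carlo margins.

# Redundancy detection and its limits

The weighted topological overlap
$\mathrm{wTO}_{ij} = |\sum_k w_{ik}w_{jk} + w_{ij}| /
(\min(\sum_k |w_{ik}|, \sum_k |w_{jk}|) + 1 - |w_{ij}|)$
(zero-diagonal Pearson association matrix $w$) scores how much of two
symptoms' neighbourhood is shared. Pairs at or above the threshold
(default 0.25, the convention of the redundancy-analysis literature) are
flagged greedily in descending order so no symptom joins two pairs.
Flagged pairs are consolidated with the minimal identified maximum
likelihood model for two indicators: a one-factor model with equal
(tau-equivalent) loadings — an unconstrained two-indicator factor model is
unidentified, so the equal-loading constraint is the smallest assumption
that makes "fit a latent variable to the pair" well-posed. Under it the
loading is $\sqrt{r}$ and the regression-method factor score is a monotone
function of $z_a + z_b$, which is returned rescaled affinely to the 0–4
severity scale. Pairs that correlate non-positively are never merged (the
model would be ill-posed); the pipeline records them as skipped.

A caveat the bundled analysis demonstrates deliberately: wTO is a
marginal-association construct. In cohorts with strong subgroup mixture
structure, co-cluster symptoms share their neighbourhood almost as
completely as true duplicate measurements do, and no threshold separates
the two (the reference cohort's top genuine-pair overlap is ~0.53, a
planted near-duplicate ~0.55). Redundancy detection at the conventional
threshold is therefore meaningful under moderate couplings — demonstrated
in `analysis/07_consolidation.R`, where a planted duplicate at wTO 0.37
stands clear of genuine pairs at ≤ 0.21 — while the reference analysis
raises its threshold to 0.55 and honestly reports zero flags.

# Numerical choices and degenerate inputs

- Glasso convergence `1e-6` relative; non-convergence is an error with the
  penalty and sweep count, never a silent partial result.
- EBIC ties on the penalty grid resolve to the larger penalty (sparser
  model).
- Walktrap dendrogram cuts use igraph's modularity maximization;
  deterministic given node order, which is why run-to-run variation is
  induced by order permutation, never by RNG inside the algorithm.
- Resamples producing a constant column are redrawn (at most 10 times,
  logged); cluster-count 0 is the recorded outcome for empty resampled
  networks.
- Constant severity columns are rejected by name everywhere; ordinal range
  violations are reported with row and column.
- Z-scores of a constant centrality vector are all zero rather than NaN.
- All file outputs are plain CSV/JSON without timestamps, so a pipeline
  rerun under the same configuration is byte-identical; the manifest
  records package version, seed, configuration and its hash.

# Known limitations

- The generator emulates the nonparanormal model exactly; real severity
  data violate it in ways the tests cannot probe (informative missingness,
  instrument effects, cohort heterogeneity beyond a finite mixture).
- The discrete-label ARI between concordance matrices is one defensible
  reading of matrix similarity; alternatives (e.g. correlation of
  vectorized matrices) would weight severity magnitude differently.
- Centralities are descriptive: no causal reading of edges or bridges is
  implied, and network comparison across subgroups is by inspection, not
  by formal tests.
- The two-indicator consolidation model is intentionally minimal; it does
  not attempt to reproduce the factor scores of any particular structural
  equation modelling software.
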