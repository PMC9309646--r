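---
title: "Regularized partial-correlation networks for ordinal symptom data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized partial-correlation networks for ordinal symptom data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ordinet` estimates a Gaussian graphical model (GGM) over questionnaire
items answered on a 5-point Likert scale. Nodes are items; the edge between
items $i$ and $j$ is their *regularized partial correlation* — the
association that remains after conditioning on every other item. Writing
$\Theta$ for the precision (inverse covariance) matrix, edges are

$$\rho_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}}.$$

Because Likert responses are ordinal and usually skewed, the input to the
estimator is the matrix $S$ of Spearman rank correlations (average ranks
under ties), not Pearson correlations. Rank-based correlation matrices need
not be positive semidefinite, so $S$ is repaired when necessary by clipping
its eigenvalues at a small floor ($10^{-8}$) and rescaling to unit diagonal
(`nearest_positive_semidefinite()`); the repair is recorded on the object
and in the run log.

Sparsity comes from the graphical lasso: $\hat\Theta$ maximizes

$$\log\det\Theta - \operatorname{tr}(S\Theta) - \lambda \sum_{i\neq j}
|\Theta_{ij}|,$$

with the diagonal unpenalized (variances are not model-selection targets
when the input is a correlation matrix). The solver is a block
coordinate-descent algorithm on the working covariance with an exact
soft-thresholding inner loop, written in C++; small partial covariances are
estimated as *exact* zeros, so the edge set needs no post-hoc thresholding.
Convergence is declared when the largest per-sweep change of the working
covariance falls below `tol` ($10^{-6}$ by default); non-convergence raises
an error naming the offending $\lambda$. At $\lambda = 0$ the estimate
equals $S^{-1}$; at $\lambda \ge \max_{i<j}|S_{ij}|$ the network is empty.

The penalty is chosen by the extended Bayesian information criterion over a
log-spaced path of 100 values from $\lambda_{\max} = \max_{i<j}|S_{ij}|$
down to $0.01\,\lambda_{\max}$:

$$\mathrm{EBIC}_\gamma = -2L + E\log n + 4\gamma E \log p,$$

where $L = (n/2)(\log\det\Theta - \operatorname{tr}(S\Theta))$, $E$ is the
number of nonzero upper-triangle partial correlations, and $\gamma \in
[0,1]$ trades sensitivity against specificity. The default $\gamma = 0.5$
is the conservative standard in network psychometrics. Descriptions of the
"regularization hyperparameter ranging from 0 to 1" in applied reports
correspond to $\gamma$, not to $\lambda$, which has no natural 0–1 range
and is tuned automatically; `ordinet` adopts that interpretation. EBIC ties
along the path are resolved toward the sparser (larger-$\lambda$) fit.
When every off-diagonal correlation is zero the path degenerates to the
single value 0 with a warning.

## Centrality and node selection

Two node-importance statistics are computed, both on the signed weights:

* **Expected influence (EI)**: $\mathrm{ei}_i = \sum_{j \neq i} \rho_{ij}$,
  the one-step signed sum of a node's edges. The one-step form is used
  because it is the quantity practitioners report for networks containing
  negative edges; no two-step variant is provided.
* **Bridge expected influence (BEI)**: the same sum restricted to edges
  that cross between the two *pre-defined* clusters (e.g. an
  intolerance-of-uncertainty cluster and a problematic-smartphone-use
  cluster). Exactly two clusters are required.

Both are reported raw and z-scored ($n-1$ standard deviation; a constant
vector z-scores to all zeros with a warning). "Central" and "bridge" nodes
are flagged by a blind percentile cutoff: the
$\lfloor p\,(1-\mathrm{percentile}/100)\rfloor$ highest-valued nodes, so 21
nodes at the default 85th percentile give exactly 3 of each. Ties at the
boundary are broken by stable node order and logged — with discrete data
exact ties are possible, and a deterministic rule keeps runs reproducible.
Selection is invariant to adding a constant, so raw and z-scored values
select identical nodes.

## Bootstrap accuracy and stability

* **Edge CIs**: `nonparametric_boot()` draws $B$ (default 2,000)
  n-out-of-n row resamples and re-runs the *entire* estimation — Spearman,
  PSD repair, glasso path, EBIC selection — on each; `edge_cis()` reports
  the empirical $\alpha/2$ and $1-\alpha/2$ quantiles per edge
  ($\alpha = 0.05$).
* **Difference tests**: two edges (or two node centralities) differ
  significantly when the bootstrap CI of their replicate-wise difference
  excludes zero. CIs are uncorrected for multiplicity by default, matching
  common reporting practice; a Bonferroni option exists but is off.
* **Case-dropping stability**: for each drop proportion $q$ in
  $\{0.05, 0.10, \ldots, 0.75\}$, $B$ subsamples of
  $\mathrm{round}((1-q)n)$ rows are drawn *without* replacement, the
  pipeline re-run, and the Pearson correlation between subsample and
  full-sample centrality recorded (Pearson because the statistic is a
  continuous vector; the choice is stored in the spec). The
  **CS-coefficient** is the largest $q$ at which at least 95% of
  replicates correlate $\ge 0.7$ with the full sample; 0.25 is the
  conventional minimum and 0.5 the ideal. Because the grid caps at 0.75,
  0.75 is the attainable maximum. Proportions leaving fewer than $p+1$
  rows are skipped with a warning; undefined correlations (constant
  statistic) and failed replicates are recorded as missing and count
  *against* the CS rule.

Reproducibility is strict: every replicate's seed is derived
deterministically from the master seed and the replicate index, so results
are bit-identical for a given seed regardless of scheduling, and replicates
that fail to converge are dropped (logged; more than 5% failing is an
error), never imputed.

## The synthetic generator

No raw survey data ships with the package, so every pipeline stage is
validated against a generator with a *known* ground truth. The model is
latent-Gaussian with per-item thresholds: draw $z \sim N(0, \Sigma)$, where
$\Sigma$ is the correlation matrix implied by a planted sparse
partial-correlation network, then cut each coordinate into codes 1–5.
Thresholds come from a two-parameter family, $\mathrm{cuts} = m + s\,(-1.5,
-0.5, 0.5, 1.5)$, solved numerically so the implied categorical mean
matches a target within 0.01 and the SD within 0.05. The two-parameter
family is identifiable from mean/SD targets alone; skew then *emerges* from
the location shift rather than being fitted, which is why generated items
reproduce target means and SDs closely but only the direction, not the
magnitude, of strongly skewed items' asymmetry.

The default profile (`iu_psu_moments()`, `make_ground_truth()` defaults)
emulates a published two-cluster survey setting: 12 + 9 items, n = 1,849,
item means 1.5–3.8 and SDs 0.8–1.1, about two thirds of all 210 possible
edges present, 15 small negative edges, anchor edges 0.43 (strongest
within cluster 1), 0.31 (strongest within cluster 2), a planted strongest
bridge edge 0.11, and a −0.05 negative bridge. Filler edges are drawn
uniformly (0.015–0.10 within, 0.015–0.06 between); the second cluster is
kept all-positive inside. The implied precision matrix is checked for
positive definiteness with margin $10^{-3}$ and, if infeasible, all
weights are shrunk proportionally with the factor recorded — the default
profile needs no shrinking. An attention-check mechanism appends two
honesty-check columns whose failure probability per row is exact, so the
row filter can be exercised end-to-end.

What the generator does *not* emulate: full category frequencies (only
first and second moments are targeted), response styles such as
acquiescence, item wordings, any non-Gaussian dependence (the copula is
Gaussian by construction), and scale-level reliability — the planted
network is not constrained to a strong one-factor structure per cluster,
so McDonald's omega on generated data is well below what real symptom
scales show. Tests passing on synthetic data therefore
show that the estimator recovers structure under the stated model, not
that any particular substantive conclusion holds in real data.

## Validation design choices and problem sizes

* **Solver oracle**: the test suite solves the same penalized likelihood
  with an independent ADMM algorithm on ≥ 20 random 4–6-node instances and
  requires elementwise agreement to $10^{-4}$.
* **Structure recovery**: on the sparse-truth configuration (every planted
  edge $|\rho| \ge 0.1$, continuous latent samples, n = 2,000) the suite
  requires sensitivity ≥ 0.9 and a false-positive rate over true non-edges
  ≤ 0.1. On the dense default profile — where the truth contains dozens of
  edges far below detectability — "false-edge rate" is assessed as the
  false-discovery proportion among reported edges (the rate at which a
  reported edge is false), since a non-edge false-positive rate conflates
  misses of tiny true edges with genuine false alarms under a 66%-dense
  truth; both numbers are reported by the acceptance script.
* **Coverage**: bootstrap CIs are checked against the *estimand of the
  pipeline* — the population partial correlation of the Spearman
  correlation of the discretized items (computed once by a 400,000-row
  Monte Carlo evaluation) — rather than the latent-scale weight, because
  discretization attenuates the latent value and a rank-based pipeline
  cannot (and does not claim to) estimate it. Sizes: 200 datasets of
  n = 500 on a 5-node truth, B = 250.
* **Stability**: the CS criterion is exercised at B = 250 on the default
  profile at n = 2,000 — large enough for the statistic, small enough to
  keep the full suite in minutes.

## Known limitations

* Spearman (not polychoric) input follows standard applied practice for
  skewed Likert data; polychoric correlations would target the latent
  scale but are out of scope.
* The penalized estimates are reported as-is; there is no unpenalized
  refit at the selected support, so edge weights are biased toward zero —
  a property shared by the applied literature this workflow mirrors, and
  the reason bootstrap CIs are interpreted against the pipeline's own
  estimand.
* Percentile bootstrap CIs for lasso-penalized quantities are approximate;
  they describe sampling variability of the regularized estimate.
* The CS-coefficient depends on its grid; values above 0.75 are not
  distinguishable under the default grid.
* Cross-sectional, between-subject networks only: no temporal, directed,
  or moderated variants, and no polychoric/mixed-data models.
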