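---
title: "Learning sparse connectomes from smooth signals: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning sparse connectomes from smooth signals: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SparseConnectome)
```

## The problem

Resting-state functional connectivity is conventionally estimated from
pairwise correlations between regional BOLD time series, which produces dense
matrices that must be thresholded ad hoc and whose edges confound direct with
indirect coupling. This package takes the graph-learning route instead: each
subject's connectome is the solution of an optimization problem that balances
a data-fidelity term against sparsity- and connectivity-promoting penalties,
so that sparsification is part of the estimator rather than a post hoc cut,
and is subject-specific by construction.

The downstream analysis is deliberately simple and interpretable: local
(node-level) graph metrics as features, mass-univariate Welch tests with
false-discovery-rate control to pick discriminative nodes, and a linear SVM
under leave-one-out cross-validation to quantify how much group information
those nodes carry.

## The graph-learning model

For a subject with time series $X \in \mathbb{R}^{T \times N}$ (rows =
timepoints, columns = regions), the pairwise squared-distance matrix is
$Z_{ij} = \lVert x_i - x_j \rVert_2^2$. The connectome is the minimizer over
symmetric, nonnegative, zero-diagonal $W$ of

$$
\lVert W \circ Z \rVert_{1,1}
\;-\; \alpha \sum_i \log d_i
\;+\; \beta \lVert W \rVert_F^2,
\qquad d_i = \sum_j W_{ij},
$$

the log-degree formulation of graph learning under a smooth-signal
assumption: regions with similar time series (small $Z_{ij}$) attract weight,
the log barrier forces every node to keep strictly positive degree (no
isolated regions), and the Frobenius term controls the spread of weights.
The data-fidelity term is required for $Z$ to enter the problem at all; a
formulation without it would return the same graph for every subject, which
is incompatible with the method's purpose of subject-specific estimation, so
the full objective above is what this package implements.

After solving, the weights are rescaled by $\delta = 2$, symmetrized, and
entries below $0.03$ (including any numerically negative values) are set to
zero — the fixed operating point $\alpha = \beta = 1$, $\delta = 2$,
threshold $0.03$ is the package default (`graphLearningParams()`), with all
four knobs exposed.

### Solver

The problem is solved on the vectorized upper triangle by a primal-dual
forward-backward-forward splitting with the linear degree operator
($\lVert S \rVert_2 = \sqrt{2(N-1)}$), a deterministic warm start (the exact
per-edge dyad solution), and step size $0.9 / (4\beta + \lVert S \rVert)$.
Numerical choices that matter:

* **Normalized units.** The wrapper solves with $\tilde z = z / c$,
  $\tilde\beta = \beta / c^2$, $c = \operatorname{mean}(z)$, and rescales
  the solution by $1/c$ — an exact identity of the objective, not an
  approximation. Raw distance scales in the hundreds otherwise slow the
  iteration by orders of magnitude.
* **Stopping.** Converged when the relative objective change *and* the
  relative change of the active iterates both fall below `tol` (default
  `1e-6`). Edges below $10^{-3}$ of the largest weight are excluded from the
  iterate criterion: weights converging to the $w = 0$ boundary decay only
  sublinearly and would otherwise block convergence despite being
  numerically (and after pruning, exactly) zero. Hitting `maxIter` (default
  50000; iterations cost microseconds) is an error, not a warning.
* **Accuracy.** At `tol = 1e-10` the solver matches a generic projected
  quasi-Newton oracle to better than $10^{-6}$ relative objective on random
  small instances, and the $N = 2$ closed form
  $w = (-z + \sqrt{z^2 + 8\alpha\beta})/(4\beta)$ to $10^{-9}$.

`pruneThreshold = Inf` legally produces an empty graph; distances may be
computed on raw (default) or per-region standardized series
(`standardizeROIs`), the latter erroring on constant regions.

## Node metrics

Six local metrics are computed per connectome (`computeAllMetrics()` returns
them as one `SummarizedExperiment`, nodes × subjects, one assay per metric).
Degree and clustering follow their binary textbook definitions on the
binarized post-pruning graph; betweenness, nodal distance and local
efficiency use edge lengths $1/W_{ij}$ on the weighted graph; betweenness
sums over ordered pairs and is unnormalized by default (a
$(N-1)(N-2)$-normalized variant is a flag). Unreachable pairs contribute 0
to betweenness and efficiency and are excluded from the distance mean, so
disconnected graphs never produce infinities.

Local assortativity uses the excess-degree decomposition
$r_i = j_i (j_i + 1) (\bar k_i - \mu_q) / (2 M \sigma_q^2)$, where $j_i$ is
the node's remaining degree, $\bar k_i$ the mean remaining degree of its
neighbours, and $\mu_q, \sigma_q^2$ the mean and *population* variance of
the remaining-degree distribution over edge stubs. This form was chosen
because it is the standard per-node decomposition of Newman's global
coefficient — $\sum_i r_i$ equals global degree assortativity exactly
whenever $\sigma_q > 0$, which the test suite asserts against an independent
implementation — and because published statements of the formula are often
typographically mangled; the decomposition property pins the intended
definition down unambiguously. Regular graphs ($\sigma_q = 0$) return all
zeros by convention.

All six metrics are validated against exhaustive brute-force enumeration
(simple-path search, Floyd–Warshall) on random graphs of up to 7 nodes.

## Selection and classification

Per metric, Welch's two-sample $t$-test (case minus control) runs at every
node; Benjamini–Hochberg at $q = 0.05$ flags significant nodes; nodes are
ranked by ascending raw $p$ (ties broken by lower node index — the ranking
is unchanged under the adjustment, which is monotone) and the top $k$
(default 5, swept 1–5) feed a linear SVM with cost $C = 1$ and class weights
inversely proportional to class frequencies (the "uniform prior" contract
for imbalanced groups). Features are z-scored with means and standard
deviations fitted on the training fold only; zero-variance columns pass
through centred.

Two selection modes exist because the right one is genuinely ambiguous in
practice:

* **nested** (default): selection is re-run inside every LOOCV training
  fold, so no information about the held-out subject reaches the feature
  ranking. This is the honest generalization estimate.
* **global**: selection once on the full sample, then LOOCV on the fixed
  node set — the literal select-then-validate ordering many papers describe.
  It is provided to *quantify* the leakage gap, and on pure-noise cohorts it
  is systematically optimistic relative to nested (the package's leakage
  canary asserts this).

A subtlety worth knowing: under LOOCV on null data, accuracy tends to fall
slightly *below* chance — removing a case subject tilts the training class
balance toward controls, biasing the prediction against the held-out class.
This is a well-documented cross-validation artifact, not a bug; the null
tests therefore check "not significantly above chance" rather than a
two-sided band around the majority rate.

Welch's statistic is computed vectorized from the closed form (verified
against `stats::t.test` to $10^{-12}$); BH via `stats::p.adjust` (verified
against the definitional step-up). At the table level, a node constant in
both groups gets $t = 0$, $p = 1$ with a warning instead of aborting the
cohort — the scalar `welchTTest()` keeps the strict error contract.

## The synthetic cohort generator

No public imaging data ships with (or is needed by) the package: every claim
is exercised on synthetic cohorts whose ground truth is known
(`cohortSpec()` / `generateCohort()`).

* **Template.** One random-geometric graph on the unit square per cohort,
  radius set for mean degree ≈ 6 (sparse, spatially structured — the regime
  learned connectomes live in), redrawn until connected, edge weights
  uniform in $(0.5, 1.5)$.
* **Subjects.** Each subject rewires 5% of the template's edges by
  degree-preserving double-edge swaps (weights travel with the edges), so
  individual topology varies while the degree sequence stays matched across
  groups.
* **Planted effect.** Case subjects attach 3 extra edges from each of 5
  planted nodes to uniformly chosen non-neighbours outside the planted set:
  the expected binarized degree difference at planted nodes is *exactly* 3,
  while each non-planted node absorbs only $5 \cdot 3 / 45 \approx 0.33$
  expected extra stubs. Other metrics (efficiency, clustering, ...) shift at
  planted nodes only as a side effect, so tests about them assert detection,
  not effect sizes. `plantedExtraEdges = 0` yields an exact null cohort.
* **Signals.** Each timepoint is an independent draw of the low-pass graph
  filter $(I + \tau L)^{-1}$ applied to white noise ($\tau = 5$), plus
  observation noise (sd 0.02). Timepoints are i.i.d. on purpose: the
  learner consumes only pairwise distances, which depend on the spatial
  covariance and not on temporal order, so modelling autocorrelation would
  add realism the estimand cannot see. The filtered signal is scaled to RMS
  0.3, which at $T = 140$ puts mean squared distances at $O(10)$ — the
  regime where the unit-regularized learner returns graphs of density
  comparable to the template. These constants were fixed once, when the
  generator was designed, by checking the generator against its own purpose
  (template recovery beats a density-matched thresholded correlation
  baseline in edge-set F1 on the majority of draws).
* **Cohort shape.** Defaults are 74 cases + 98 controls, $T = 140$, 50
  nodes. Group sizes and the scan-length floor mirror a realistic
  single-site cohort; 50 nodes (rather than an atlas-scale 200) keeps a
  full 172-subject cohort analysable in seconds without changing any
  qualitative behaviour of the method. Age and sex columns are fillers the
  pipeline core never reads.

What the generator does *not* emulate — hemodynamics, temporal
autocorrelation, scanner/site effects, motion artifacts, atlas
misparcellation — bounds what green tests mean: they validate the
*method* (recovery of planted topological effects from signals that satisfy
its smoothness assumption), not performance on real BOLD data.

## Validation at the study scale

The acceptance suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) runs the full pipeline on cohorts at the default
scale, 20 seeds for the planted condition and 5 for the null:

* all 5 planted nodes appear in the degree metric's FDR-significant set in
  ≥ 90% of seeds;
* nested-LOOCV accuracy for degree (~0.95 on average) exceeds every other
  metric's, matching the qualitative ordering expected when the group
  difference is planted in degree;
* null cohorts show no metric significantly above chance, and global-mode
  selection is optimistic relative to nested (leakage gap ≈ 0.05–0.10);
* Welch $p$-values are KS-uniform under the null and the empirical FDR of
  the selection stage stays at $q$ within Monte-Carlo error;
* every learned connectome is symmetric, zero-diagonal, with no retained
  weight below 0.03.

## Known limitations

* The log-degree objective fixes $\alpha = \beta = 1$ by convention; no
  per-dataset sensitivity analysis is automated (the parameters are exposed
  for one).
* The solver's error contract on `maxIter` is strict; pathological inputs
  (all-zero distance rows with adversarial structure) surface as errors
  rather than silent results.
* Violin-plot data are exported as tidy tables; plotting itself is left to
  the user.
* Nothing here should be read as a claim about classification accuracy on
  real rs-fMRI cohorts; the package validates machinery, and real-data
  accuracy depends on preprocessing, site effects and parcellation choices
  that are out of scope.
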