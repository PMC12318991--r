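---
title: "Methods: multi-task Grey Wolf feature selection with counterfactual explanation"
author: "fcselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task Grey Wolf feature selection with counterfactual explanation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcselect)
```

## The problem

Functional connectivity (FC) studies of psychiatric disease summarize each
subject's resting-state fMRI as an N x N matrix of Pearson correlations
between region-of-interest (ROI) time series.  With the 90-region AAL
parcellation this yields q = N(N-1)/2 = 4,005 edge features per subject,
while typical case-control cohorts contain only tens to low hundreds of
subjects.  Classifying patients against controls in this regime demands
aggressive, stable feature selection, and clinical use additionally demands
interpretability: which edges drive the prediction, and how would a
patient's connectivity have to change for the classifier to consider them
normal?

`fcselect` addresses both with a single pipeline: hybrid filter weighting of
edges, knee-point stratification of the ranked weight curve, probabilistic
generation of related selection tasks, a binary multi-task Grey Wolf
Optimizer (GWO) with cross-task knowledge transfer, a linear maximum-margin
classifier, and diverse counterfactual examples for individual subjects.

## Edge features

`compute_fc_matrix()` correlates ROI time-series columns (Pearson; the field
standard, and consistent with FC values reported as raw correlations — no
Fisher z-transform is applied).  `vectorize_upper()` takes the strictly
upper triangle in row-major order over pairs (a, b), a < b; the ordering is
deterministic and `devectorize()` inverts it exactly.  Labels are coded
0 = patient, 1 = control throughout.

## Feature weighting

Three univariate scores are computed per edge j:

* Fisher criterion: $h_j = |\mu_{j,0}-\mu_{j,1}|^2 / (\sigma_{j,0}^2 +
  \sigma_{j,1}^2 + \varepsilon)$, with population (divide-by-count)
  variances and $\varepsilon = 10^{-12}$ guarding constant features.
* Mutual information $m_j$ between the feature, discretized into 10
  equal-frequency bins, and the label, in nats with the $0\log 0 = 0$
  convention.  A normalized variant (divide by the label entropy) is
  available via `normalize_mi`; the raw double-sum is the default because
  the plain definition is what the combined weight consumes.
* Population standard deviation $\sigma_j$, rewarding dispersed edges.

The combined weight is $s_j = \alpha_1 \tilde h_j + \alpha_2 \tilde m_j +
\alpha_3 \tilde\sigma_j$ with defaults $\alpha = (0.4, 0.4, 0.2)$.  The raw
components live on very different scales (Fisher scores are unbounded,
MI is bounded by $\ln 2$ for a binary label, dispersions are on the FC
scale), so each component is min-max normalized across features before
weighting; otherwise the alphas would be meaningless.  `raw_components =
TRUE` restores the literal unnormalized combination.  Ties in the ranking
are broken by the smaller feature index, everywhere.

### Knee points and strata

On the descending weight curve (x = rank, y = weight), a knee is the
interior point at maximal perpendicular distance from the chord joining the
first and last points.  One knee is defined by that rule; a second is
obtained by applying the same rule to the sub-curve strictly after the
first — this keeps the procedure deterministic and yields the three strata
used for reporting: core (before the first knee), important (between the
knees), remaining (after the second).  A flat or perfectly linear
(sub-)curve has no knee (maximal distance below $10^{-12}$) and the strata
collapse gracefully: the partition is always exhaustive and disjoint.

### Task generation

Weights become selection probabilities $P_j = \omega_j / \sum\omega$ and
adjusted probabilities $P'_j = P_j / \max P$, so the best edge has
$P' = 1$.  Each of n tasks (default 8) draws one threshold
$\lambda \sim U(0,1)$ and keeps every feature with $\lambda \le P'_j$.  The
one-draw-per-task reading means each task is a nested "probability slice":
low thresholds produce broad tasks, high thresholds produce focused ones,
and top-weighted features recur in every task.  An alternative reading —
one independent draw per feature (`mode = "per_feature_lambda"`) — is also
implemented; both have the same marginal inclusion frequency $P'_j$, which
the test suite verifies empirically to within 0.02 over 10,000 tasks.
Empty tasks are redrawn (at most 100 consecutive retries).

## Multi-task Grey Wolf optimization

Each task is a binary subset-selection problem over its candidate edges.
Wolves are continuous positions in $[0,1]^{q_{task}}$ decoded by a 0.5
threshold; the three best-so-far binary solutions (alpha, beta, delta) guide
every wolf through the encircling update
$X \leftarrow \tfrac13\sum_{i} (X_i - A_i |C_i X_i - X|)$ with
$A = 2dr_1 - d$, $C = 2r_2$, and $d = 2(1 - t/t_{max})$ decaying linearly
from 2 to 0.  Leaders are elitist (kept in the comparison pool), so the
best-so-far fitness trace is non-decreasing by construction.  The
0.5-threshold decode was chosen over a sigmoid transfer function as the
simplest deterministic rule consistent with the binary initialization.

Fitness of a mask is $\rho \cdot ACC - (1-\rho) \cdot q_{sf}/q_{task}$
(default $\rho = 0.9$): inner-CV accuracy of the linear margin classifier
penalized by relative subset size.  Accuracy uses stratified 3-fold CV **on
the training split only**, with the fold assignment drawn once per task and
reused for every evaluation, and results memoized by mask — this keeps the
fitness a deterministic function of the mask, which both bounds cost and
makes runs exactly reproducible.  The penalty denominator is the task's
candidate count by default (`penalty_scope = "global"` uses q instead): the
task-local reading keeps the penalty per selected feature comparable across
tasks of different breadth.  An empty mask scores -1.

### Knowledge transfer

Tasks are solved sequentially.  A knowledge base accumulates, per feature,
how many earlier task solutions selected it; the next task's pack is
initialized by independent Bernoulli draws with probabilities
$counts/\sum counts$, floored at 0.05 so features with no history are never
permanently extinct.  The first task (or every task when transfer is
disabled, the ablation condition) falls back to the weight-based $P'$.  The
counts record solution membership, not candidate membership: what transfers
between tasks is which edges *won*, not which were offered.

### Aggregation

The n per-task best subsets must become one.  The default is majority
voting (selected by more than n/2 of task bests), falling back to the
best-fitness task's subset when the majority set is empty; `aggregate =
"best"` and `"union"` are available.  Majority was chosen because transfer
deliberately correlates the tasks, making cross-task recurrence a
meaningful stability signal.

### What the optimizer converges to — and what it does not

The parsimony term makes the optimizer prefer the *smallest* subset
achieving top inner-CV accuracy.  On synthetic cohorts with strongly
separable planted edges this is a single edge: every additional planted
edge costs $(1-\rho)/q_{task}$ fitness and buys no accuracy, so the
converged best mask typically contains one or two planted edges — chosen
with near-perfect precision (the acceptance script reports the fraction of
runs whose selected subset lies entirely inside the planted set), but by
design it does not reproduce the full planted set.  Recall of the complete
planted set is therefore *not* a property of this fitness; precision and
held-out accuracy are.  Users who want broader edge panels (e.g. for
biomarker reporting) should read the per-task selection frequencies or use
`aggregate = "union"` rather than raising $\rho$ to 1.

## Classification and evaluation

The classifier is a soft-margin linear SVM (via `e1071`, `scale = FALSE`,
fixed C = 1 — no kernel or hyperparameter search, deliberately, given the
small-sample regime).  The fitted object exposes the primal weights
oriented so that decision value $w \cdot x + b \ge 0$ predicts control.
`cross_validate_pipeline()` runs stratified 5-fold CV in which the entire
selection pipeline is re-fit on each training portion (nested, leak-free,
the default); a leaky mode that selects once on the full data exists only
to demonstrate the leakage effect on null data.  Sensitivity and
specificity treat the patient class (label 0) as positive, the clinical
convention; a flag flips it.

Cohort demographic tables are checked with the matching classical tests:
Pearson chi-square *without* continuity correction for 2 x 2 sex ratios and
the pooled-variance (not Welch) two-sample t-test from printed age
summaries — these two choices reproduce published cohort p-values exactly,
which pins down the conventions.  The paired two-sided t-test for method
comparisons reports (t = 0, p = 1) when all differences vanish.

## Diverse counterfactual examples

For a subject with profile $c$ (restricted to the k selected edges), L
candidates $x^1 \dots x^L$ (default L = 10) are optimized jointly to
minimize

$$\frac1L\sum_l \max(0, 1 - z \cdot (w \cdot x^l + b))
  \;+\; \gamma_1 \frac1L\sum_l \mathrm{dist}(x^l, c)
  \;-\; \gamma_2 \det(K),$$

with $z = +1$ for target class control, $\mathrm{dist}(x, c) =
\frac1k\sum_j |x_j - c_j| / MAD_j$ (per-feature median absolute deviations
over the training set; zero MADs fall back to the population sd, then to
1), and $K_{uv} = 1/(1 + \mathrm{dist}(x^u, x^v))$.  Defaults
$\gamma_1 = 0.5$, $\gamma_2 = 1$.  The distance averages over the k
features (so it is a per-candidate quantity usable inside the kernel);
`normalize_by = "L"` divides by the candidate count instead, for the
variant in which the constant is read as the candidate count.

Numerical choices:

* Candidates are initialized as $c + N(0, 0.1^2)$ and updated by fixed-step
  (learning rate 0.05, at most 1000 iterations) proximal-subgradient
  descent.  Gradients are taken per candidate — the objective's $1/L$
  averaging is absorbed into the step, so the step scale does not shrink
  with L (with the literal averaged gradient, a learning rate of 0.05
  cannot cross a unit margin within the iteration budget).
* The hinge term contributes its analytic subgradient $-z w$ while the
  margin is violated.
* The L1 proximity term is applied through its exact proximal operator —
  soft-thresholding toward $c$ by $\mathrm{lr} \cdot \gamma_1 / (k \cdot
  MAD_j)$ per feature.  A raw L1 subgradient under a fixed step oscillates
  around unchanged features with amplitude proportional to $\gamma_1$,
  which inverts the expected "larger $\gamma_1$, closer counterfactuals"
  monotonicity; the proximal step leaves untouched features exactly at
  their observed values, which is also the clinically desirable behaviour.
* The diversity term uses the exact determinant gradient
  $\partial \det(K) = \det(K)\,\mathrm{tr}(K^{-1}\partial K)$ rather than
  finite differences: it is exact and needs one $O(L^2 k)$ pass.
* The kernel diagonal receives a small uniform jitter in $[0, 10^{-4}]$ to
  keep the determinant well defined for near-duplicate candidates.  The
  jitter is drawn once per call (seeded) and held fixed during descent, so
  the objective being minimized is a fixed deterministic function.
* Candidate values are *not* box-constrained by default: a counterfactual
  FC value may legitimately leave $[-1, 1]$, and published counterfactual
  FC analyses report such values.  `clip_range` restores a box if wanted.
* Only the k selected edges are perturbed; all other edges stay at their
  observed values.
* The descent stops early only when every candidate is valid (predicted as
  the target class) and the relative objective change falls below
  $10^{-5}$.

Validity of a candidate means the model predicts the target class; a zero
hinge loss (margin at least 1) is sufficient but not necessary.
`change_report()` tabulates per-candidate, per-edge original and
counterfactual values with increase/decrease/unchanged directions
(|delta| < $10^{-6}$ counts as unchanged).

## The synthetic connectome generator

Because clinical FC cohorts are not redistributable, the generator is the
package's test bed.  In `"features"` mode every edge is i.i.d.
$N(0, \sigma^2)$ in both classes except D planted edges whose class-0 mean
is shifted by $+\Delta$; in `"timeseries"` mode subjects get
multivariate-normal ROI series whose population correlation differs by
about $\Delta$ on planted, ROI-disjoint edge pairs (disjointness keeps the
covariance positive definite), and FC matrices are computed per subject.
Defaults emulate a compact cohort: N = 20 ROIs (190 edges), 40 + 40
subjects, D = 5, $\Delta = 1.5$, noise sd 0.3 — a strong, cleanly planted
effect.  Everything is deterministic given the seed.

What the generator does *not* emulate: spatial correlation among edges
sharing an ROI, site/scanner effects, heavy-tailed motion artifacts, class
imbalance, or label noise.  Passing tests on this generator demonstrates
algorithmic correctness and the intended statistical behaviour of each
stage, not clinical-grade performance on real cohorts.

## Problem sizes used by the test suite and acceptance script

GWO budgets in the automated runs are deliberately compact — pack sizes
6–15 and 3–25 iterations on the 190-edge problems, 4 tasks for nested CV —
chosen as the smallest budgets at which the optimizer's properties
(monotone traces, optimum attainment on separable data, transfer gains,
held-out accuracy) are stable across seeds; the package defaults
(pack 30, $t_{max}$ = 100, n = 8 tasks) remain the recommended settings for
real analyses.  Counterfactual descent in tests uses 300 iterations, which
suffices for unit-margin crossings at the default learning rate on the
fixtures used.

## Known limitations

* The optimizer's parsimony pressure (see above) means the aggregated
  subset is a minimal discriminative panel, not an exhaustive abnormality
  map.
* Gradient-based counterfactual descent requires the unscaled linear
  decision value; nonlinear kernels are out of scope.
* The MI estimator is a fixed-bin discretizer; continuous k-NN estimators
  are deliberately not provided.
* Task generation with one lambda per task yields nested candidate sets;
  diversity between tasks comes from the threshold, not from independent
  sampling.  The per-feature mode trades this for unstructured diversity.
* Five-fold nested CV re-runs the whole selection pipeline per fold; on a
  4,005-edge, 100-subject problem with default budgets this is minutes of
  compute, not seconds.
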