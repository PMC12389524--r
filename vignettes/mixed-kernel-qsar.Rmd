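---
title: "Mixed-kernel SVR QSAR modeling with CLPSO tuning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-kernel SVR QSAR modeling with CLPSO tuning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarmix)
```

## The modeling problem

qsarmix builds quantitative structure–activity relationship (QSAR)
regressions that map molecular descriptors — numeric features computed from
a compound's structure — to inhibitory potency, expressed as lg(IC50) with
IC50 in nM. The motivating application is inhibitors of the triple-mutant
epidermal growth factor receptor (EGFR L858R/T790M/C797S), the resistance
variant that defeats third-generation inhibitors such as Osimertinib, but
nothing in the package is specific to that target: any descriptor table with
a real-valued response fits the interfaces.

The package ships a reference table of 92 such inhibitors — measured
lg(IC50) plus the predictions of six published models (a heuristic linear
model, random forest, gene expression programming, gradient boosting,
polynomial-kernel SVR and mixed-kernel SVR) with a fixed 73/19 train/test
split. The per-compound *descriptor* values behind those models were never
published, so the models themselves cannot be refit from public data. That
constraint shapes the package's validation strategy: statistics that can be
recomputed from the reference table are recomputed exactly, and everything
else — solvers, optimizers, selectors, validators — is verified on synthetic
data with known ground truth.

## The mixed-kernel support vector regression model

The core model is epsilon-insensitive support vector regression (SVR).
Given training pairs \((x_i, y_i)\), the dual problem is

\[
\min_{\alpha,\alpha^*}\;
\tfrac12 (\alpha-\alpha^*)^\top K (\alpha-\alpha^*)
+ \varepsilon \sum_i (\alpha_i + \alpha_i^*)
- \sum_i y_i (\alpha_i - \alpha_i^*)
\quad
\text{s.t. } \textstyle\sum_i (\alpha_i - \alpha_i^*) = 0,\;
0 \le \alpha_i, \alpha_i^* \le C ,
\]

with predictor \(f(x) = \sum_j (\alpha_j - \alpha_j^*) K(x_j, x) + b\). The
cost \(C > 0\) trades flatness against violations of the
\(\pm\varepsilon\) tube.

Three base kernels are provided, plus their convex combination:

* linear: \(K(x,y) = x \cdot y\) — a global kernel, strong generalization,
  weak learning capacity;
* polynomial: \(K(x,y) = (\gamma\, x \cdot y + r)^d\), \(\gamma > 0\) —
  global, with capacity controlled by the degree \(d\);
* trigonometric: \(K(x,y) = \sin(\pi/2 + \sigma \lVert x-y\rVert^2)\),
  \(\sigma > 0\) — a local, high-capacity kernel with unit diagonal. Small
  \(\sigma\) suits sparse data, large \(\sigma\) compact data;
* mixed: \(\alpha K_{trig} + \beta K_{poly} + (1-\alpha-\beta) K_{lin}\)
  with \(\alpha, \beta \in [0,1]\), \(\alpha + \beta \le 1\), balancing the
  local kernel's learning ability against the global kernels'
  generalization.

The squared norm in the trigonometric kernel is the squared Euclidean
distance; this gives \(K(x,x) = 1\) and a smooth surface, consistent with
how this kernel family is defined in the kernel-methods literature.

### Numerical choices

**Indefiniteness.** The trigonometric kernel is not provably positive
semidefinite, and on real data its Gram matrices do carry negative
eigenvalues (one of the unit tests constructs such a case). Before the dual
solve the training Gram is projected onto the PSD cone by clipping negative
eigenvalues at zero; the clipped spectral mass is recorded on the fitted
model, and prediction uses the *original* kernel. This keeps the QP convex
and reproducible at the cost of a small, measured perturbation of the
training objective.

**Standardization.** Descriptors are z-scored by training means and
standard deviations inside `svr_train()` and identically at prediction
time. The kernel length-scales (\(\sigma\), \(\gamma\)) are only meaningful
on a fixed input scale, so scaling is the model layer's job — the kernels
themselves never rescale.

**Solver.** The dual is solved by sequential minimal optimization over the
2n-variable form with maximal-violating-pair selection. Stopping uses the
standard KKT-violation gap, interpreted relative to the kernel scale:
with polynomial components such as \(\gamma \approx 10\) and \(d = 3\) on
standardized data, Gram entries reach \(10^6\)–\(10^8\) and an absolute
\(10^{-3}\) gap is below what double-precision gradients can resolve. For
kernels of order 1 the criterion is effectively absolute; the test suite
verifies agreement with an independent projected-gradient QP solver to
\(10^{-6}\) relative objective there. The gradient is recomputed from
scratch every \(4n\) updates to cancel incremental drift. The bias is
averaged over free support vectors, falling back to the midpoint of the
KKT-feasible interval.

## Hyperparameter search: comprehensive-learning PSO

The mixed-kernel model has seven interacting hyperparameters
(\(C, \varepsilon, \sigma, \gamma, r, d, \alpha, \beta\) with the simplex
constraint), which motivates a population-based optimizer. In plain PSO each
particle is pulled toward its personal best and the global best; when local
optima abound this collapses diversity early. The comprehensive-learning
variant (CLPSO) instead lets *every dimension* of every particle learn from
a possibly different particle's personal best:

\[ V_d \leftarrow \omega V_d + c \cdot rand_d \cdot
   (pbest_{exemplar(d),d} - X_d). \]

Exemplars are drawn per dimension: with probability \(Pc_i\) the better of
two randomly chosen particles' personal bests, otherwise the particle's own;
if all dimensions self-assign, one random dimension is forced to another
particle. Exemplars are refreshed once a particle has failed to improve for
more than the refreshing gap.

Defaults follow the original CLPSO literature and are all configurable:
\(Pc_i = 0.05 + 0.45\,(e^{10(i-1)/(ps-1)}-1)/(e^{10}-1)\), refreshing gap 7,
\(c = 1.49445\), inertia decreasing linearly 0.9 → 0.4 over the evaluation
budget, velocity clamped to 20% of each dimension's range. Positions are
clamped to the box with the velocity zeroed in clamped dimensions. Integer
dimensions (e.g. the polynomial degree, tree counts) keep real-valued swarm
positions and are rounded only at fitness evaluation and reporting, which
preserves the swarm dynamics.

**Convergence trade-off.** Comprehensive learning buys diversity at the
price of slow unimodal convergence — the property is inherent, not an
implementation artifact. Measured on this implementation: a 5-D quadratic
bowl needs roughly 3000–5000 evaluations for the swarm to reach \(10^{-2}\)
to \(10^{-3}\), where plain PSO manages in 500; conversely on a 10-D
multimodal surface of cosine wells at a 10,000–20,000 evaluation budget
CLPSO's median final fitness is far below plain PSO's (the test suite
asserts the comparison at 10,000). Budgets in the examples and tests are
chosen accordingly: 1-D recoveries use 500 evaluations, the 5-D bowl 3000,
the multimodal comparison 10,000, and the SVR tuning runs 360 evaluations
of 3-fold cross-validation, which suffices because many kernel
configurations fit the noise-free synthetic target well.

**Cross-validation fitness.** `cv_fitness()` freezes a seeded fold
assignment at creation, so the returned closure is deterministic; it maps a
position to pooled out-of-fold RMSE (or \(1 - Q^2\)). Infeasible mixed
weights (\(\alpha + \beta > 1\)) are repaired by Euclidean projection onto
the simplex face and counted. SVR solves inside the fitness use a modest
iteration cap: positions whose duals cannot approach optimality quickly
produce poor fitness and the swarm simply moves away, while the final refit
runs at full budget. Results are cached by rounded position.

## Tree ensembles and descriptor selection

The regression trees are exact greedy CART under squared error: candidate
thresholds are midpoints between consecutive sorted unique values, and each
split records its improvement \(\tau^2\) (parent SSE minus child SSEs). Ties
in gain break by (feature index, threshold) lexicographic order, making
fits fully deterministic. Gradient boosting fits each stage to the current
residuals with a shrinkage factor; random forests average trees fit on
seeded bootstrap resamples (feature subsampling is available but defaults to
all features, matching the four-hyperparameter RF convention).

Split-gain importance accumulates \(\tau^2\) per feature within a tree and
averages the per-tree sums across the ensemble. `select_descriptors()`
ranks by that importance and walks the ranking, keeping a descriptor only
if its absolute Pearson correlation with every kept descriptor is below 0.8
— the standard multicollinearity guard for QSAR descriptor sets. The number
of descriptors kept, `k`, is an explicit argument; the report includes
successive importance ratios so a caller can apply the usual "gap in the
importance curve" heuristic instead of a fixed k. This mirrors gradient
-boosting-based feature selection as practiced with XGBoost-style gain
importances; regularized gain variants and SHAP analyses are out of scope.

## The linear-QSAR path

`prefilter_descriptors()` applies the conventional pre-selection rules, in
order: drop constant columns; drop descriptors whose one-parameter
regression F statistic is below 1.0; resolve descriptor pairs correlated
above 0.8 by keeping the one with higher single-descriptor \(R^2\); drop
descriptors with one-parameter |t| below a user-specified floor (default
1.96). Each removal is logged with its rule and statistic. Forward
selection then grows OLS models greedily by training \(R^2\), reporting for
each size the cross-validated \(R^2_{cv}\) computed by the exact PRESS
identity (equivalent to leave-one-out refitting, but deterministic and
O(1) per model), which supports the familiar elbow analysis of descriptor
count versus quality.

The published three-descriptor linear model for the EGFR inhibitor series is
exposed directly as `apply_hm_model(rs, nr, me)` (relative sulfur count,
ring count, maximum C–N exchange energy) so its predictions can be
reproduced without the proprietary descriptor software that selected those
descriptors. The heuristic-method software itself is proprietary; the
pre-filter plus forward selection implemented here is the generic analog,
and the original descriptor choice is not reproducible without the original
descriptor values.

## Validation and applicability domain

`r_squared()` is \(1 - SSE/SST\) (not squared Pearson correlation): this
definition, applied to the reference table's mixed-kernel column,
reproduces the published test statistics to within the table's 2-decimal
rounding, which is how the package fixes the convention. Internal
validation uses leave-one-out and k-fold \(Q^2\) (seeded shuffle,
contiguous folds, pooled out-of-fold predictions; \(k = n\) reduces exactly
to LOO). The \(Q^2\) denominators center on the full-sample response mean.
External validation uses Lin's concordance correlation coefficient and
\(Q^2_{F1}\)/\(Q^2_{F2}\), which differ in whether test responses are
centered on the training or test mean. y-randomization refits the model on
seeded permutations of the response, reporting each scrambled fit's training
\(R^2\) and LOO \(Q^2\); a sound model shows low values in every repeat.
Default acceptability thresholds are the conventional
\(R^2 > 0.7\), \(Q^2_{LOO} > 0.6\), \(Q^2_{5fold} > 0.55\), \(CCC > 0.85\),
\(Q^2_F > 0.7\).

The applicability domain uses the leverage method:
\(h_i = x_i^\top (X^\top X)^{-1} x_i\) against the warning leverage
\(h^* = 3p/n\), with \(p\) counting descriptors plus intercept and \(n\)
the training-set size. Standardized residuals divide by the standard
deviation of the *training* residuals (the \(\sigma\) of the usual
\(\pm3\sigma\) band). Williams classification: |standardized residual| > 3
is a response outlier; leverage above \(h^*\) with residual inside the band
is an influential (structurally unusual but well-predicted) compound;
everything else is in-domain.

## The synthetic-data generator

`make_synthetic_dataset()` emulates the statistical structure QSAR
descriptor selection assumes: informative descriptors (i.i.d. standard
normal) that drive the response, redundant descriptors correlated with an
informative parent at a configurable level above 0.8 (so a correct
correlation filter must drop them), and pure-noise descriptors. The linear
response is a fixed linear combination; the nonlinear response is a sum of
cosines of scaled squared distances to a few anchor points drawn from the
data distribution — bounded, smooth, and by construction inside the
trigonometric kernel's hypothesis class, so a tuned mixed-kernel SVR has a
realizable target and recovery is a meaningful test. Response noise is
Gaussian with configurable sd (default 0.1 lg units, a realistic assay
noise scale for log-potency data; the redundancy default of 0.95 represents
the strongly collinear descriptor pairs typical of large descriptor suites).
Ground truth is returned separately from the table so tests never read it
through the modeling API.

What the generator does *not* emulate: realistic descriptor marginals
(heavy tails, discreteness, block correlation of real constitutional or
quantum-chemical descriptors), structure–descriptor consistency, or
measurement error in the descriptors themselves. Passing tests on this
generator therefore demonstrate correctness of the algorithms under
controlled conditions, not predictive performance on new chemistry.

## Problem sizes and budgets used by the tests

Module tests run on 10–200 compounds with 1–10 descriptors; the
QP-oracle comparison uses twenty problems of 4–8 points; the tuning
demonstration uses 120 compounds, a 4:1 split, 3-fold cross-validation and
a 360-evaluation CLPSO budget (12 particles); the multimodal
CLPSO-vs-PSO comparison uses 10 dimensions, 12 seeds and 10,000
evaluations. These sizes were chosen so the full suite exercises every code
path at statistically meaningful sizes while remaining comfortably
runnable on a laptop.

## Known limitations

* The trigonometric/mixed Gram is clipped to PSD for training; models whose
  clipped mass is large relative to the spectrum should be treated with
  care (the value is recorded on the model).
* CLPSO is the right tool for rugged hyperparameter landscapes, not for
  fast local refinement; for smooth low-dimensional problems plain PSO (also
  provided) converges far faster.
* The reference table's non-MIX model columns are internally inconsistent
  with their published summary statistics (`reproduce_table6()` reports
  them as mismatches by design); only the mixed-kernel column is used as a
  numerical anchor.
* Published CCC/\(Q^2_{F1}\)/\(Q^2_{F2}\) for the mixed-kernel model do not
  match recomputation from the 19 printed test rows (the evaluation set
  behind those statistics is unreported); the package's implementations are
  verified against hand-computed examples and exact identities instead.
* Descriptor *computation* from structures is out of scope; inputs are
  numeric descriptor tables.
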