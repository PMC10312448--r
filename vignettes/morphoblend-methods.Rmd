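---
title: "Classifying landmark-based shape phenotypes with blending ensembles"
author: "morphoblend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying landmark-based shape phenotypes with blending ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoblend)
```

## The problem

Geometric morphometrics describes biological form as configurations of
`p` homologous landmarks in `k` dimensions. Classifying such phenotypes —
assigning specimens to sexes, species, populations, habitats, or
genotypes from their shape alone — is increasingly a high-dimensional
problem: modern datasets carry hundreds of coordinates, many classes,
unequal class covariances, and non-linear class boundaries, conditions
under which the traditional linear discriminant is no longer a safe
default. No single learning algorithm wins across such datasets, and
picking an algorithm because it won on someone else's data is a flawed
strategy. `morphoblend` instead implements a *blending ensemble*
workflow: train a diverse registry of base classifiers, rank them by a
resampled optimization metric, and stack the top performers' held-out
validation predictions under a second-stage metalearner.

## The workflow

### Procrustes superimposition

Raw landmark configurations confound shape with nuisance position,
orientation, and size. `gpa_align()` removes these by generalized
Procrustes analysis: each configuration is translated to a zero
centroid, scaled to unit centroid size, and rotated (proper rotations
only — landmark data distinguish chirality, so reflections are never
allowed) to minimize its squared distance to the consensus, which is
iteratively re-estimated.

Two conventions matter and are deliberate:

* **Partial Procrustes scaling.** Every configuration keeps unit
  centroid size; no further shape-dependent rescaling is applied. This
  is the common default of the major morphometrics toolkits and keeps
  centroid sizes interpretable as the size variable that was removed.
* **Consensus = arithmetic mean.** The consensus is the plain mean of
  the aligned configurations, not re-normalized to unit size. The
  iteration is then exact block coordinate descent on the Procrustes sum
  of squares — rotations minimize it given the consensus, the mean
  minimizes it given the rotations — so the recorded objective trace is
  provably non-increasing and convergence (default tolerance `1e-10`,
  at most 100 iterations) is well defined. Non-convergence is reported
  as a flag, never an error.

Because a Procrustes solution is only determined up to one global
rotation, the final solution is put in a canonical orientation: the
consensus is rotated onto its principal axes with a deterministic,
proper-rotation sign rule. Alignment output is therefore invariant to
arbitrary nuisance transformations of the input specimens — a property
the test suite checks to `1e-6` — rather than invariant merely up to
rotation.

The aligned coordinates are flattened row-major by landmark
(`x1, y1[, z1], x2, ...`), a fixed order that downstream variable
importances rely on. These flattened Procrustes coordinates are used
directly as the Euclidean ("tangent space") representation; a formal
orthogonal projection at the consensus is available via
`tangent_project = TRUE` but is off by default, since for the small
shape variation typical of within-taxon data the two differ negligibly.

### Anomaly filtering

Outliers are flagged by the classical morphometric rule: a specimen's
Procrustes distance to the consensus beyond `Q3 + 1.5 * IQR` of the
distance distribution (`procrustes_iqr_filter()`; the multiplier is
Tukey's conventional fence and is configurable, `Inf` disables removal).
The filter is a single pass: re-running it on the retained specimens
against the same consensus removes nothing further, and the consensus is
deliberately not recomputed inside the filter, so no recursive trimming
occurs. Removal also never empties a class; specimens whose removal
would do so are retained with a warning. More generic anomaly scores —
any per-specimen real vector, e.g. from the in-package isolation forest
(`isolation_scores()`) — can be screened against the Procrustes
distances with `anomaly_score_correlation()`, but removal decisions are
made only by the distance rule.

### Partitioning and feature extraction

`stratified_split()` implements the blending split as a two-stage
per-class allocation: `round(0.15 * n_c)` of each class to the test set,
then `round(0.15 * remaining)` to the validation set, the rest to
training (rounding half away from zero, minimum one specimen per class
in test and validation). This realizes an 85/15 train/test split with
15% of the training data reserved for validation; a one-shot 70/15/15
allocation is available as `scheme = "direct"`. For a single class of
101 specimens the two-stage scheme yields 15/13/73 — the validation set
of 13 is exactly what this split produces at that sample size, a useful
arithmetic anchor for correctness.

`pca_fit()` is fitted **on the training partition only** (SVD of the
centered training matrix; covariance denominator `n - 1`) and retains
the smallest number of leading components whose cumulative
explained-variance ratio reaches the threshold (default 0.95, a
conventional choice). Validation and test data are projected into that
space with `pca_project()`; they never influence the decomposition.

### Base learners and tuning

`default_registry()` provides a family-spanning set of classifiers —
Bayesian (naive Bayes), trees (CART, random forest), bagging/boosting
(bagged trees, SAMME adaptive boosting), discriminant analysis (LDA,
QDA, and a regularized variant that blends per-class with pooled
covariances and shrinks toward a scaled identity), kernel/instance
methods (k-NN; linear, polynomial, and RBF support vector machines), a
single-hidden-layer neural network, and regression methods (penalized
multinomial regression, plain logistic regression for binary tasks,
PLS-DA). Standard implementations are used wherever an established
package provides one; the regularized discriminant and the SAMME
booster are implemented in-package. Learners that only exist for
two-class problems are flagged `binary_only` and excluded from
multi-class registries. Hyperparameter spaces are fixed, documented
discrete grids (log-spaced SVM costs, `mtry` fractions, odd `k` up to
31, and so on); they are sensible defaults, not reproductions of any
other tool's internal heuristics.

`random_search_tune()` draws up to `tune_length` (default 10) distinct
combinations uniformly from a learner's grid and evaluates each with
`resample_evaluate()`: `B = 25` bootstrap resamples by default, fitting
on the resample and scoring on the out-of-bag specimens, with optional
up-/down-sampling inside each resample to redress class imbalance.
Every candidate is scored on the *same* resamples, so candidate
comparisons are paired. The default optimization metric is ROC AUC for
binary tasks and Cohen's kappa for multi-class ones; log loss, accuracy,
balanced accuracy, and F1 are available. Ties go to the first drawn
candidate; failed candidates are skipped, and a learner whose every
candidate fails is excluded downstream. All randomness flows from one
master seed through named substreams (`derive_seed`), so tuning distinct
learners in any order — or concurrently — reproduces identical results.

### Blending

`train_blend()` takes the top `k` leaderboard entries (members that fail
to predict the validation partition are dropped and the next entry
promoted), stacks their per-class validation probabilities into a
`k x C`-column matrix, and fits the metalearner on it: a ridge-penalized
(multinomial) logistic regression (`lambda = 1e-4`, chosen small but
non-zero to survive the collinear member blocks) or a 500-tree random
forest. Probabilities, not hard labels, are stacked by default — they
preserve calibration information and are the dominant stacking
convention — with a one-hot mode for comparison. Test data never enter
the blend's training path; they are seen only by `predict_blend()`.

Two numerical choices deserve note. The ridge metalearner does **not**
standardize the stacked columns: probabilities already share the
`[0, 1]` scale, and per-column standardization would inflate the raw
coefficients of near-constant blocks, corrupting the member weights read
off them. And degenerate stacks are handled explicitly — constant
columns are excluded from the forest metalearner's split search, and a
stack with no varying column at all falls back to a class-prior
predictor rather than failing.

Member model-importance weights are the sum of absolute metalearner
coefficients (glm, summed across outcome equations) or impurity
importances (rf) over each member's column block, normalized to one.
`ensemble_importance()` then multiplies each member's normalized
per-variable importances by its weight and sums: a weighted mean
importance per input variable, summing to one. For members without a
native importance measure, a one-vs-rest AUC filter importance is used.

### Evaluation

`confusion_matrix()` cross-tabulates predicted against observed classes
(rows = predicted). `binary_metrics()` evaluates the standard suite —
precision, sensitivity, specificity, F1, balanced accuracy, prevalence,
detection rate, detection prevalence, PPV, NPV, accuracy, kappa — and
`multiclass_metrics()` aggregates per-class one-vs-rest values as
unweighted macro means (micro averaging is available). Zero-denominator
ratios are reported as missing and excluded from macro means, never
silently coerced to zero. `relative_rank()` maps within-dataset method
ranks (average ranks for ties) linearly onto `[-1, 1]` so that rank
profiles can be averaged across datasets. Cohen's kappa is exposed as
`cohen_kappa()` (the name `kappa` belongs to base R's condition-number
estimator).

### Dataset-level properties and meta-regression

To explain *why* performance varies across datasets, `dataset_properties()`
summarizes each dataset by: the multivariate R² of shape on class
(`class_r2()`, `1 - SS_within / SS_total`, with an optional
label-permutation p-value — the point estimate itself is deterministic);
the mean Frobenius distance between class covariance matrices
(`mean_class_cov_distance()`); the mean Procrustes distance between
class mean shapes (`mean_class_shape_distance()`); the quotient of the
between- and within-class covariance traces (`variance_ratio()`, both on
the `n - 1` denominator so that `trace(B) + trace(W)` equals the total
covariance trace exactly — a unit test); class balance as Shannon
entropy normalized by `ln C` (base-free); and sample size.
`meta_regression()` then regresses a performance metric (in percentage
points) on a task indicator plus one property, reporting the property
effect per conventional unit (0.1 for most properties, 0.01 for shape
distance, 1 for sample size) alongside the residual SE, F statistic,
and R².

## The synthetic-data generator

`generate_landmarks()` emulates the statistical structure of real
landmark datasets so every stage is testable without downloads: class
mean shapes are built by displacing a template (regular polygon in 2D,
spiral in 3D) along centered random fields, rescaled by root-finding so
consecutive class means sit at a prescribed Procrustes distance `delta`
(verified internally to `1e-6`); specimens are class mean plus i.i.d.
Gaussian landmark noise with per-class multipliers; nuisance rotation
(uniform on the rotation group), translation (uniform in a width-10
cube), and scaling (log-uniform in `[0.5, 2]`) are applied per specimen.
Class geometry draws from a seed stream separate from specimen noise, so
the same class structure can be re-noised reproducibly.

What it does **not** emulate: landmark-wise correlation structure
(real shape covariance is far from isotropic), digitization error that
varies by landmark, allometry, measurement batches, and non-Gaussian
within-class variation. Passing tests on these fixtures therefore
demonstrate correctness of the machinery and recoverability of known
structure, not expected performance on any particular real dataset.

## Numerical choices and checked properties

* Alignment is verified against an independent brute-force oracle: for
  2D pairs, the Procrustes distance equals the minimum over a
  `1e-4`-radian grid of rotation angles to within `1e-6`.
* The split's arithmetic anchors (15/13/73 at `n = 101`; per-class
  8/6/36 for two classes of 50) are asserted exactly, as is seed
  determinism and class-proportionate allocation.
* Metric formulas are asserted against hand-evaluated 2×2 and 3×3
  confusion tables to `1e-12`.
* Parameter recovery: a generating mean-shape separation of 0.08 is
  recovered by `mean_class_shape_distance()` within 15% at 500
  specimens per class; `class_r2()` vanishes (< 0.05) when classes share
  a mean.
* Null calibration: with labels independent of features, mean resampled
  kappa stays within ±0.1 of zero and macro balanced accuracy within
  0.45–0.55 over 25 bootstrap resamples.
* The blending claim is exercised end-to-end on 20 seeded two-class
  datasets with moderate class overlap: mean-shape separation 0.12 at
  landmark noise 0.05 (for 20 coordinates this puts the Bayes error
  near 11%, i.e. achievable balanced accuracy around 0.89 — genuinely
  overlapping classes rather than a ceiling regime), 400 specimens per
  class so the 120-specimen test sets estimate balanced accuracy with a
  standard error near 0.03. Under a reduced six-learner registry (tune
  length 3, B = 10) the top-3 glm blend matches or beats the base
  learners' mean balanced accuracy and stays within 0.05 of the best
  base learner on every dataset. These problem sizes were chosen so the
  comparison measures the ensemble, not estimator noise: with much
  smaller test sets, the maximum of six noisy base-learner estimates is
  upward-biased by more than the margin being tested.

## A small worked example

```{r example, eval = FALSE}
sp <- synthetic_spec(n_classes = 2, class_counts = 150, p = 10,
                     delta = 0.1, noise_sd = 0.05, seed = 42)
dataset <- generate_landmarks(sp)
cfg <- run_config(registry = c("lda", "qda", "knn", "cart", "nb", "glmnet"),
                  tune_length = 3, resampling = list(type = "bootstrap", B = 10),
                  top_k = 3, metalearners = "glm", seed = 42)
res <- run_pipeline(dataset, cfg)
res$metrics
res$properties
```

The same workflow is exposed as a command line
(`inst/cli/morphoblend`, or `mb_cli()` from R) with subcommands
`simulate`, `preprocess`, `train`, `blend`, `evaluate`, `meta`, and
`run-all`, each writing plain-text artifacts plus a `manifest.json`
recording the full configuration and seed for bit-identical reruns.

## Known limitations

* Semilandmark sliding, missing-landmark estimation, bilateral-symmetry
  decomposition, and allometric size correction are out of scope; input
  configurations must be complete and homologous.
* The blending split trains the metalearner on a single held-out
  validation set. For very small datasets the validation partition can
  shrink to a handful of specimens per class and the metalearner
  estimate becomes noisy — the 13-specimen validation set at `n = 101`
  is a realistic warning case. Cross-validated (out-of-fold) stacking is
  deliberately not implemented.
* The default registry is a representative, family-spanning set of
  around fifteen learners, not a reproduction of any specific larger
  collection; the registry is open — any `learner_spec()` can be added.
* Member model-importance weights read block coefficients off the
  metalearner; this is a documented interpretive choice, and other
  weightings (e.g. validation-metric weights) are easy to substitute.
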