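---
title: "Optimisation-based pathway activity inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimisation-based pathway activity inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dioptra)
```

## The problem

Gene-level expression matrices are wide (thousands of genes) and shallow
(hundreds of samples), which makes phenotype classifiers unstable and hard
to interpret. Pathway activity inference collapses the expression of each
curated gene set into a single per-sample score, reducing dimensionality to
a few hundred biologically meaningful features. Most published scores are
unsupervised summaries (mean expression, first principal component,
enrichment statistics); they capture variance, not class structure.

This package takes the supervised, optimisation-based route. For each
pathway it learns, by mixed-integer linear programming (MILP), the signed
gene weighting whose induced activity score separates the phenotype
classes as well as possible, together with an explicit activity interval
per class.

## The model

For one pathway with member genes $m$ and samples $s$ with class labels
$c_s$, the activity is the weighted linear combination

$$pa_s = \sum_m G_{sm}\,(rp_m - rn_m),$$

where $G_{sm}$ is the expression value and $rp_m, rn_m \in [0, 1]$ are the
positive and negative weight components. A binary $L_m$ enforces
$rp_m \le L_m$ and $rn_m \le 1 - L_m$, so at most one component is
positive per gene, and the absolute weights are normalised,
$\sum_m (rp_m + rn_m) = 1$.

Each class $c$ receives an interval $[LO_c, UP_c]$ of width at least
$\varepsilon$; for every pair $k < c$ a binary $Y_{kc}$ together with a
big-M constant $U$ decides which interval lies above the other, with a
separation of at least $\varepsilon$ either way. A sample's violation
distance

$$D_s \ge \max(0,\; LO_{c_s} - pa_s,\; pa_s - UP_{c_s})$$

is zero when its activity falls inside its own class interval, and the
objective minimises $z = \sum_s D_s$. At an optimum, samples of the same
class cluster inside their interval and the residual objective measures
how inseparable the classes are along any unit-$\ell_1$ weighting of the
pathway's genes.

Compared with formulations that force every sample inside its class range
through per-sample binaries, expressing misclassification as a continuous
distance leaves only $M + \binom{C}{2}$ binaries per model, which is what
makes proving optimality practical.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `epsilon` | minimum interval width and class separation, in activity units (same scale as expression) | `1e-3` | far below FPKM-like magnitudes, far above solver tolerance |
| `big_M` | deactivation constant for the ordering constraints | `"auto"` | derived per pathway from the expression scale (below) |
| `time_limit_s` | solver wall-clock budget per model | 200 s | an incumbent at the limit is returned as `FEASIBLE` with its gap |
| `relative_gap_target` | MIP gap at which the solver may stop | 0 | prove optimality unless told otherwise |
| `max_zero_fraction` | gene missingness filter | 0.30 | genes with *strictly more* than 30% zeros are dropped |

The missingness filter treats zero as the only missingness sentinel
(FPKM-like data); `NA`/`NaN` in the input are rejected at parse time.
The filter is applied once to the full input matrix, before any
cross-validation split: it depends only on per-gene zero counts, not on
labels, so applying it per training fold would change the gene universe
across folds without protecting against leakage of class information.
Expression values are used as provided; no internal log transform is
applied.

## Numerical choices

**Big-M and variable bounds.** Because $\sum_m(rp_m + rn_m) = 1$, every
activity satisfies $|pa_s| \le \max|G|$. The exported
`resolve_big_M()` returns the reference scale $2\max|G| + 3\varepsilon$.
Internally the model builder derives a consistent pair: interval
variables are bounded at $\pm(\max|G| + (2C+1)\varepsilon)$ and the
deactivation constant is set to twice that bound plus $\varepsilon$. The
pairing matters: a deactivated ordering constraint must be slack at
*every* feasible corner of the interval boxes, which requires
$U \ge (UP_k - LO_c)_{\max} + \varepsilon = 2\,\text{bound} +
\varepsilon$. The bound itself cannot cut any optimum: intervals lying
wholly outside the activity range can always be translated toward it
without increasing any violation distance, and at most $C$ minimal-width
intervals ever need to stack beyond the data range, which the
$(2C+1)\varepsilon$ slack accommodates for any expression scale,
including an all-zero matrix.

**Symmetry breaking.** Every solution has a mirror twin obtained by
flipping all weight signs and reflecting the intervals. The builder fixes
the first gene's sign binary to 1, halving the branch-and-bound tree;
since the mirrored copy of any optimum satisfies the fixed binary, no
optimal objective is lost. Reported weight vectors may therefore differ
in global sign from an unconstrained formulation — any optimum is an
acceptable answer, and ties among alternative optima are accepted as-is.

**Solver backends.** The default backend solves the MILP with HiGHS
through a batched subprocess bridge (`inst/python/milp_solver.py`):
models are serialised in sparse triplet JSON, solved in one interpreter
per batch, and read back. `fit_dioptra()` sends all pathways of one
training fold as a single batch, so interpreter start-up is paid once per
fold rather than once per pathway. A proven optimum maps to status
`OPTIMAL`; an incumbent at the time limit to `FEASIBLE` with its relative
gap; no incumbent to `NO_SOLUTION` (never a silent zero). The
`"enumerate"` backend solves tiny instances exactly by enumerating the
binaries; it exists for environments and tests where a second,
independent route is wanted.

**The optimality oracle.** `brute_force_optimum()` certifies solver
results on small instances: with the $L_m$ signs and the interval
ordering fixed, the model is a linear program, so enumerating all $2^M$
sign vectors and $C!$ orderings and taking the best LP optimum yields the
global minimum. The LPs are solved by a bundled two-phase dense simplex
with Bland's rule — a deliberately independent code path from HiGHS. The
guard (at most 6 genes, 3 classes) bounds the $2^M C!$ LP solves.
Degenerate single-class instances keep the width constraint, skip the
vacuous pairwise constraints and solve to objective zero.

## Model-native classification

A fitted pathway model classifies directly, with no external learner:
a sample's activity is allocated to the class interval with the smallest
violation distance (ties to the first class in sorted order), and the
*individual pathway prediction accuracy* is the fraction of samples
allocated to their labelled class. Across pathways, the *combined
prediction* lets each solved pathway vote with its allocation; the
predicted class has the highest vote fraction, with ties broken first by
the smaller summed violation distance over the tied pathways, then by
class sort order. Pathways whose solve returned `NO_SOLUTION` have no
intervals and are excluded from the vote denominator. The tie-break
rules are not scientifically meaningful; they exist so that repeated
runs are bit-reproducible.

Pathways are ranked by mean individual accuracy; by default the
accuracies are computed on held-out test folds (a `ranking = "train"`
switch exists), because training-side allocation of a model fitted to
those same samples is optimistically biased. Genes are ranked within a
pathway by accumulating $|rp_m - rn_m|$ across repeated trainings; the
per-run normalisation makes the accumulated weights of one pathway sum
to the number of runs.

## Baselines and the classifier contract

Two reference scores are included: per-pathway mean expression and the
first principal component (training-mean centring, unit-norm loading,
largest-magnitude entry forced positive to fix the sign; variance
scaling is off by default, behind a flag). PCA parameters are fitted on
training folds only and projected onto test folds — the same blindness
discipline the optimisation model observes.

Baseline activities need an external classifier; the harness accepts any
object with `fit(activities, labels)` / `predict(model, activities)`.
The built-in default is a nearest-centroid classifier, kept deliberately
minimal so the core evaluation depends on no machine-learning package;
wrappers around e.g. `randomForest` drop into the same contract.
Imbalance handling beyond stratification (e.g. resampling synthesis) is
intentionally out of scope.

## Evaluation harness

`stratified_cv_split()` builds `k`-fold plans (default 10) with
`repeats` repetitions (default 3, hence 30 train/test splits), balancing
per-class counts across folds to within one; classes smaller than `k`
are spread round-robin with a warning. `run_experiment()` fits the
chosen method on each training fold, scores both folds, predicts
test-fold classes and reports accuracy plus macro-averaged precision,
recall and F1 (zero-denominator cases contribute 0; macro averaging over
the classes present in the truth, chosen as the symmetric convention for
multi-class problems), aggregated as mean and standard error over
splits. `milp_schedule()` enumerates the implied pathway-by-split solve
schedule without solving — with 279 pathways and a 3-repeat 10-fold plan
it lists 8,370 models.

The noise-robustness experiment perturbs expression by selecting a
fraction of genes (count rounded half away from zero) and permuting each
selected gene's values across samples, preserving per-gene value
multisets exactly; fraction 0 returns the input bit-identically.

## The synthetic generator

`generate_dataset()` emulates the one property of normalised RNA-seq
data the model cares about: positive, right-skewed expression with
class-dependent location for some genes. Within each pathway an
informative subset of genes receives log-space class means
$\text{sign}_m \cdot c \cdot \delta$ (random per-gene sign, so both
positive and negative optimal weights are exercised); noise genes have
mean zero; values are $\exp(\mathcal{N}(\mu, \sigma^2))$ with optional
dropout zeros. The signal-to-noise ratio $\delta/\sigma$ controls
separability: at $\delta/\sigma = 10$ class ranges on an informative
gene are disjoint by construction, at $\delta = 0$ there is no signal at
all. The generator does *not* emulate gene–gene correlation, batch
effects, library-size variation or heavy-tailed outliers; tests passing
on these fixtures demonstrate correctness of the optimisation and
harness, not expected accuracy on real tumour cohorts.

Default conditions: 3 classes × 30 samples, 10 pathways × 10 genes,
30% informative genes, $\delta = 1$, $\sigma = 0.2$, no dropout.

## Problem sizes used by the test-suite experiments

The package's own experiments are sized so that every solve proves
optimality in well under a second: oracle comparisons use up to 4 genes,
3 classes and 12 samples; the separable cross-validation study uses the
default generator conditions with $\sigma = 0.1$ over a 3×10-fold plan
(300 models); the no-signal control uses 20 pathways of 6 genes over one
10-fold plan (200 models — no-signal instances are the hardest to prove
optimal, and 6-gene models keep that proof fast); the recovery study
uses 10 seeds × 5 pathways with 3-fold training. These are the
package's chosen study conditions, stated here so results are
reproducible.

## Known limitations

* The MILP is solved per pathway independently; cross-pathway
  correlation of activities is not modelled.
* With strongly separable data the optimum is rarely unique; weight
  vectors are reproducible for a fixed solver version but not canonical.
* No-signal instances have weak LP relaxations (the lower bound stays
  near zero), so proving optimality degrades quickly beyond ~10 genes;
  the time limit then returns incumbents whose reported gaps are close
  to 1 even when the incumbent is good.
* The HiGHS backend requires a Python interpreter with scipy on the
  host; discovery order is documented in `?model_config`.
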