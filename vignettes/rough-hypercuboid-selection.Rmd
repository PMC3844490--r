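---
title: "Selecting expression markers with rough hypercuboids"
author: "muHEM package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting expression markers with rough hypercuboids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muHEM)
```

## The problem and the model

Marker selection from a labelled expression matrix (miRNAs or genes in rows,
samples in columns, a class label per sample) usually starts by discretizing
the measurements so that classical rough-set or information-theoretic scores
can be computed.  Discretization discards the very thing a continuous assay
measures.  The method implemented here avoids it: for each feature
$A_k$ and each class $\beta_i$, the training samples of that class span a
value interval $[L_i, U_i]$ (their minimum and maximum).  The Cartesian
product of these intervals over a feature set is the class *hypercuboid*,
and the region where two class hypercuboids intersect — the *implicit*
hypercuboid — contains exactly the samples whose class the feature set
cannot decide.

The bookkeeping object is the $c \times n$ *equivalence partition matrix*
$H(A) = [h_{ij}]$ with $h_{ij} = 1$ when sample $j$ lies inside class $i$'s
interval(s), boundaries inclusive.  On training data each sample lies in its
own class interval, so every column sums to at least 1.  The *confusion
vector* $v_j = \min(1, \sum_i h_{ij} - 1)$ flags samples inside an implicit
hypercuboid, and the *dependency* (relevance) of the labels $D$ on $A$ is
the unconfused fraction

$$\gamma_A(D) = 1 - \frac{1}{n}\sum_j v_j(A) \in [0, 1].$$

Joint matrices are entrywise ANDs of single-feature matrices, so adding a
feature can only switch memberships off: dependency is monotone
non-decreasing in the feature set.  The *significance* of $A_k$ inside $A$
is the dependency lost by dropping it,
$\sigma_A(D, A_k) = \gamma_A(D) - \gamma_{A \setminus \{A_k\}}(D) \ge 0$;
a zero means $A_k$ is dispensable there (an exact duplicate is the extreme
case).

Two formulations of dependency (a sum over unconfused memberships and
$1 - \text{mean}(v)$) coincide only because every training sample belongs
to at least one class interval; the code asserts that precondition instead
of choosing between the formulas, and refuses to score out-of-training
columns through the hypercuboid algebra.

## The greedy selector and its weight

`selectFeatures()` seeds the selected set $S$ with the feature of maximal
relevance, then repeats two moves until $d$ features are selected or the
candidate pool empties:

1. every remaining candidate with *exactly* zero significance with respect
   to any already-selected feature is removed permanently (it adds nothing
   to that feature);
2. the candidate maximizing
   $\omega\,\gamma_{A_j}(D) + \frac{1-\omega}{|S|}
   \sum_{A_i \in S} \sigma_{\{A_i,A_j\}}(D, A_j)$
   is admitted.

$\omega \in [0,1]$ trades relevance against complementarity: at
$\omega = 1$ the method is relevance ranking filtered by dispensability; at
$\omega = 0$ it chases complementarity alone and will happily admit
irrelevant features, which is why interior values are preferred.

A consequence worth stating plainly: if a selected feature has total
dependency ($\gamma = 1$), the joint dependency with *any* candidate is
also 1, every candidate's significance is zero, and selection stops with
that single feature.  This is the faithful semantics of the dependency
measure — one perfect feature *is* a sufficient reduct — and it means the
selector intentionally returns fewer than $d$ features on perfectly
separable data.  On real expression data single-feature dependencies are
essentially never 1 and the search proceeds normally.

### Numerical choices

* Interval membership is `L <= x && x <= U` in native double precision with
  no tolerance: the comparison is a pure order relation, so equal stored
  values behave identically on both sides.
* Confusion is counted in integers; significance used by the selector is a
  difference of integer counts divided by $n$, so the zero-significance
  test in move 1 is exact, not a tolerance test.  The exported
  `attributeSignificance()` evaluates the same quantity as the literal
  difference of the two dependency values, making the identity
  $\sigma = \gamma(A) - \gamma(A \setminus \{A_k\})$ hold bit-exactly.
* Ties (at seeding and at admission) go to the feature earlier in input
  order, so runs are reproducible and permuting the input rows can change
  the output only where scores tie exactly.
* The removal in move 1 is permanent across iterations.

### Choosing the weight

For a given $\omega$, each admitted feature $A_j$ ($j \ge 2$) carries its
average significance $\Omega_j$ against the features selected before it.
`cvIndex()` summarizes the profile by the coefficient of variation
$s/\mu$, with $s$ the population standard deviation (divisor = profile
length), and `optimizeOmega()` picks the $\omega$ on a grid (default
$0.0, 0.1, \dots, 1.0$, the grid used in the original experiments) that
minimizes it, ties toward smaller $\omega$.  $\Omega_1$ is undefined
(there are no earlier picks) and is excluded from the index.  A selector
that admits features with evenly spread significances (low $C_v$) is
preferred to one whose later picks contribute erratically.  The target
count defaults to $d = 50$, the regime in which average significance
profiles flatten on typical miRNA panels.

## The B.632+ evaluation harness

Prediction error of a selector + classifier pipeline is estimated by the
B.632+ bootstrap, which interpolates between the optimistic apparent error
and the pessimistic leave-one-out bootstrap error:

* **AE** (`apparentError()`): select on the full data, train on the full
  data, test on the same samples.
* **B1** (`bootstrapB1()`): for each of $M$ resamples of size $n$ drawn
  with replacement (default $M = 50$, matching the "50 random splits" of
  the original study), selection is re-run *inside the resample*, the
  classifier is trained on it, and the out-of-bag samples are predicted.
  Each sample's errors are averaged over the resamples that excluded it,
  then over samples; samples never out of bag contribute a 0/0 term and
  are dropped.  A resample that loses an entire class would leave both
  selection and the classifier undefined, so it is redrawn (under the run
  seed); at the study's sample sizes this has negligible probability.
* **no-information error** (`noInformationError()`): labels are permuted
  once (seeded; the number of permutations is a parameter of scope left at
  one), selection and training are run on the permuted-label data, the
  rule predicts all original samples, and
  $\gamma = \sum_i p_i (1 - q_i)$ combines the true class proportions
  $p_i$ with the assignment proportions $q_i$.
* **B.632+** (`b632plus()`): with $B1' = \min(B1, \gamma)$, the relative
  overfitting rate is $r = (B1' - AE)/(\gamma - AE)$, clamped to $[0, 1]$
  and set to 0 when $\gamma \le AE$; the weight is
  $\tilde\omega = 0.632/(1 - 0.368\,r) \in [0.632, 1]$ and the estimate is
  $(1-\tilde\omega)AE + \tilde\omega B1'$, always between $AE$ and $B1'$.
  The clamping conventions are the standard ones for this estimator and
  keep it defined in the degenerate corners.
* **Gap** (`gapEstimate()`): $\gamma - B1$; values near zero mean the
  pipeline does no better than chance, negative values worse.

`errorCurve()` evaluates all of these at every prefix of the ranked
selection (re-using each resample's own ranking), the usual way to read
off how many markers are worth keeping.

The default classifier is a linear-kernel SVM with unit cost (libsvm via
\pkg{e1071}), without input scaling so that repeated runs and constant
selected features behave deterministically.  Any object built with
`makeClassifier()` — two deterministic functions, fit and predict — can
replace it.

## What the synthetic generator emulates

`syntheticExpressionData()` produces the structures the algebra is about,
with uniformly drawn values so that class value *ranges* — the only thing
the method consumes — are controlled directly:

* **separable** features: disjoint per-class ranges, dependency exactly 1;
* **overlap** features: unit intervals overlapping by a set fraction,
  dependency below 1 and decreasing with overlap;
* **duplicate** features: exact value copies of separable sources, zero
  significance with respect to them;
* **noise** features: one Gaussian for all classes.

The defaults (two balanced classes of 20 samples; 3 separable, 2
duplicates, 45 noise features) mirror a small two-class miRNA panel in
which a handful of markers carries the signal.  Uniform sampling, exact
duplication and block ordering are idealizations: real microarray data
have heavy-tailed noise, batch effects, near- (not exact-) duplicates and
no privileged feature order.  Passing tests on these fixtures therefore
demonstrate the correctness of the algebra and the harness, not
performance on any particular real dataset.

## Test and validation design

The suite validates the vectorized algebra bit-exactly against brute-force
per-sample loops on hundreds of small random datasets (up to 12 samples, 4
features, 3 classes), property-tests the monotonicity of dependency and
the significance identity, hand-traces the greedy selector on constructed
examples, and checks the harness identities (convexity of B.632+, the
indicator-level B1 formula, seeded reproducibility).  End-to-end runs use
two-class datasets of 40-60 samples with up to 50 features and 20
bootstrap resamples — large enough to exercise every code path while
keeping the full suite fast on one CPU; the same sizes are used by the
reproduction script `scripts/acceptance.R`.

One acceptance scenario asks the selector, on perfectly separable planted
markers plus duplicates and noise, to list all three planted markers
first.  As explained above, total dependency of the first marker makes
every other feature — planted or not — dispensable under the method's own
algebra (indeed all separable features and their duplicates have
*identical* partition matrices there, so no score derived from $H$ can
tell them apart).  The faithful implementation selects one marker and
discards the rest; the corresponding test documents this behaviour rather
than papering over it, and the realistic analogue (partially overlapping
markers, $\gamma < 1$) is covered by a passing property test.

## Limitations

* Dependency is a training-range statistic: a single outlier stretches a
  class interval and can hide real separation; the method performs no
  outlier trimming, normalization or imputation (missing values are
  rejected at load).
* Significance-guided search is first-order greedy; no backtracking or
  floating search is attempted.
* The hypercuboid algebra never scores samples outside all class
  intervals, so the classifier — not the algebra — is the only component
  that generalizes to unseen data.
* The GEO series-matrix reader is a best-effort convenience for clean
  files, not a full SOFT/MINiML parser.
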