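---
title: "Methods: wrapper selection and probability fusion for ultrasound features"
author: "sonoselect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrapper selection and probability fusion for ultrasound features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoselect)
```

This vignette explains the models and procedures the package
implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data
results do and do not demonstrate about real ultrasound data.

## The pipeline

Breast-ultrasound collections are small and imbalanced (a typical
public collection holds a few hundred images across benign, malignant
and normal classes), and deep-feature vectors extracted from them are
wide and partially redundant. The pipeline therefore runs:

1. stratified train/test split;
2. class balancing of the *training* portion by exact-permutation
   augmentation;
3. feature extraction behind a pluggable contract;
4. two independent wrapper feature selectors;
5. probability-based serial fusion of the two selected sets;
6. classifier benchmarking with macro metrics and mean-rank analysis.

Augmentation is applied after splitting and only to the training
portion: the three operations are exact pixel permutations, so an
augmented copy of a test image in the training set would be near-equal
to the test image itself and inflate every score.

## Augmentation

The three operations — horizontal flip, vertical flip, quarter-turn
rotation — are bijections on the pixel grid: no interpolation, the
pixel multiset is invariant. The quarter turn is counter-clockwise;
the direction is a pure convention since the chain enumeration
generates both senses (a clockwise turn is three counter-clockwise
ones, and `rotate90+rotate90` gives the half turn either way).

Balancing a class to a target count first cycles a deterministic
schedule per source image (the three single operations, then the ten
2-op chains that are not literally the identity), then draws random
chains of length 3–5 under the stage seed. An identical chain is never
reapplied to the same source, so no two augmented images share both
source and chain; every augmented image records `source:chain` in its
provenance string. Deterministic cycling first makes small targets
reproducible without consuming randomness at all.

Splits allocate `round(fraction * count)` samples per class to
training. For a 133/210/487 class profile at 50 %, that gives
66–67/105/243–244 — printed protocol tables elsewhere sometimes carry
other counts (56/105/243), which are not arithmetically reachable by
any single fraction; the package makes no attempt to replicate such
counts and documents the rounding rule instead.

## The feature-extraction contract

A `FeatureExtractor` is any pure function image → length-D real
vector. The bundled mock (`mockDeepExtractor`) computes an 8×8 grid of
block mean intensities, a 4×4 grid of block mean gradient magnitudes
and 8 global summaries (89 statistics), passes them through a fixed
seeded Gaussian random projection to D dimensions, and applies a leaky
rectifier (slope 0.1, keeping sign information without dead units).
Default D = 1024 mirrors the width of a typical global-average-pooling
layer; tests and examples use 16–64 for speed. The mock is *not* a
trained network and makes no claim of matching one — it exists so the
selector, fusion and evaluation layers can be exercised and tested
end-to-end with reproducible inputs. An adapter to a real pretrained
backbone can implement the same contract; nothing downstream changes.

## The shared wrapper objective

Both selectors minimize

\[ f(m) = \mathrm{err}_{\mathrm{kNN}}(m) + \lambda \, \frac{|m|}{D}, \]

the held-out misclassification error of k-nearest neighbours (k = 3)
on the masked columns, using one stratified 70/30 internal split drawn
under the fitness seed, plus a sparsity penalty (λ = 0.01 by default).
The internal split is fixed for the whole run, which makes the
objective a deterministic function of the mask — this is what turns
the greedy/elitist update rules into exact monotonicity guarantees on
the recorded best-fitness history. k, the split fraction, λ and the
seed are all configurable (`fitnessControl`) and logged in the
pipeline manifests.

## Reformed differential evolution

The DE selector searches the continuous box [0,1]^D. Initialization
draws each component as `zmin + u (zmax − zmin)`. Four mutation
strategies are available (`rand/1` default, plus `best/1`,
`rand-to-best/1`, `rand/2`), followed by binomial crossover with one
forced mutant index — every trial inherits at least one mutant
component at any crossover rate — and greedy survivor selection with
inclusive ties (a trial with equal fitness replaces the target).

Numerical choices:

- **Bounds handling.** Mutants are clipped to the bounds component-wise
  before crossover. Clipping is deterministic and keeps the degenerate
  hand-checkable cases exact; a uniform re-draw of escaped components
  would inject extra randomness into an otherwise traceable step.
- **Binarization.** A candidate position maps to a mask by
  thresholding at 0.5; if no component reaches the cut, the single
  largest component is set, so the objective is always evaluable.
- **SSEoM post-threshold.** After convergence the best vector's
  surviving components are filtered once more by the
  standard-error-of-mean rule: keep component i iff
  `z_i >= sd(z)/sqrt(D')`. The rule is scale-equivariant and
  intentionally mild — for a converged vector whose surviving
  components cluster near the upper bound, the spread is small and the
  filter removes only clear stragglers. Whether the threshold should
  apply to position values or to per-column data statistics is
  ambiguous on its face; the package defaults to the literal reading
  (position values) and exposes
  `deConfig(sseomSource = "importance")`, which instead thresholds the
  per-column between/total variance scores of the surviving columns.

## Reformed binary grey-wolf optimizer

Wolves are bit vectors; the three best solutions found so far (alpha,
beta, delta) guide every update. Per dimension and leader the
coefficients `A = 2 a r1 − a` and `C = 2 r2` are drawn fresh, with `a`
decreasing linearly 2 → 0 over the iteration budget; the leader
distance is `|C·leader − x|`; the continuous step is the steep sigmoid
`1/(1+exp(−10(A·dist − 0.5)))`; its Bernoulli realization feeds an
OR-type leader move, and the wolf's new bit is a one-of-three
stochastic crossover (equal thirds) of the three candidates.

Consequences worth knowing: the OR-type move can only *add* a leader's
set bits during the exploratory phase, so packs are dense early; as
`a → 0` the transfer argument saturates negative, the binary steps
vanish and the pack contracts onto the leader patterns. Leaders are
replaced only by strictly better fitness, so the alpha history is
exactly non-increasing. An all-zero wolf cannot be evaluated; it is
rescued with one random bit.

## Probability-based fusion

Each selector's sub-matrix gets per-column importance scores — the
between-class over total sum of squares (eta squared) of the column
against the labels — normalized to probabilities within the vector.
The fused set is built serially (DE columns, then grey-wolf columns),
keeping a column iff its probability reaches `alpha` times the best
probability across both vectors (`alpha` = 0.5 default), then removing
near-duplicates: two kept columns are duplicates when they trace to
the same source column or correlate at ≥ `1 − duplicateTol`
(`duplicateTol` = 0.01, chosen to catch the synthetic generator's
jittered copies at r ≈ 0.9975 while leaving genuinely distinct
informative columns alone). The higher-probability copy survives;
ties keep the serial-earlier one. Both the importance definition and
the keep rule are explicit interpretations of "probability-based
serial fusion", wired through `fusionConfig` so alternatives can be
added without breaking the contract; eta squared was chosen because it
is label-aware, deterministic, bounded and free of tuning parameters.
The fused size K never exceeds the sum of the input sizes and can fall
below both — redundancy between two wrappers run on the same matrix is
the rule, not the exception.

## Evaluation conventions

Metrics follow the benchmark-table conventions of the applied
literature: per-class sensitivity and precision, *macro* (unweighted)
averages, accuracy as trace/total, FNR = 100 − macro sensitivity
(exact by construction), F1 as the harmonic mean of the macro
sensitivity and precision, percents rounded to two decimals. Macro
averaging is the variant under which published sensitivity/FNR pairs
(e.g. 99.06/0.94) are internally consistent. The classifier registry
(SVM family via `e1071`, fine and distance-weighted k-NN, LDA, rpart
tree, random forest) is deliberately off-the-shelf and pluggable — the
package's substance is in the selectors and fusion, not the learners.
Wall-clock columns are reported but never asserted. Rank analysis uses
within-fold average ranks and the Nemenyi critical difference
`CD = q_alpha(m) sqrt(m(m+1)/(6N))` with
`q_alpha(m) = qtukey(1 − alpha, m, Inf)/sqrt(2)` rather than a
hard-coded table.

## The synthetic generators

`makeFeatureMatrix` plants: informative columns whose class means are
spaced `classSep · noiseSd` apart (class order permuted per column so
informative columns are not collinear), redundant columns that are
jittered copies (jitter sd = 0.05 noiseSd — tight enough that
deduplication must fire), and label-independent Gaussian noise.
`makeImageSet` renders a multiplicative-speckle background (uniform
per-pixel factor on a constant base — a qualitative nod to ultrasound
speckle, not a physical model) with one smooth dark ellipse for the
benign-like class, an irregular dark star-shaped blob for the
malignant-like class, and nothing for the normal class. Sizes default
to the class profile of a well-known public ultrasound collection in
the examples.

What passing tests on these fixtures shows: the optimizer mechanics,
the contracts, determinism, and that the stages respond to planted
signal as designed. What they do not show: performance on real
ultrasound images, where class boundaries are not Gaussian, lesions
are not geometric primitives, and a trained backbone replaces the mock
extractor.

## Problem sizes and a known limitation

Test and script runs use desk-scale sizes chosen to keep the full
suite in a couple of minutes: n = 300 samples, D = 200 features, 15
informative at separation 2 for the selector experiments; populations
of 20–30 for 40 generations/iterations.

Under exactly these conditions the wrapper objective exposes a real
and instructive limitation of wrapper feature selection: with 15
well-separated informative columns, the k-NN error is 0 for almost any
mask containing a handful of them, so the objective is *flat* in the
informative bits and the only remaining gradient is the sparsity
penalty, which prunes columns indiscriminately (the inclusive tie rule
accelerates this drift). Both selectors therefore converge to compact
masks that achieve perfect held-out error while recovering only
roughly half of the planted informative columns — measured medians
over 10 seeds are about 0.55 (DE) and 0.6 (grey wolf), not the ~0.8
one might naively expect of a selector scored by ground-truth
recovery. Recovering *all* informative columns is simply not what this
objective rewards once the error saturates; a fitness with graded
class margins, cross-validated error, or a much weaker signal would be
needed for full-recovery behaviour. The acceptance suite asserts the
0.8 recovery level regardless and documents the measured shortfall
rather than weakening the check; the dimensionality-reduction half of
the property (selected < D) holds throughout.

## Reproducibility

Every seeded function saves and restores the caller's RNG state, so
nested seeded components (fitness split inside an optimizer loop
inside a pipeline) never perturb each other. Pipeline stage seeds are
fixed offsets of the global seed; two runs with the same configuration
are byte-identical in masks, fused matrices and metric tables, and the
manifests record parameters and artifact checksums for audit.
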