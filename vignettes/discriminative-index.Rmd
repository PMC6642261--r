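---
title: "Ranking genes by Discriminative Index: model, assumptions and design"
author: "DIselect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking genes by Discriminative Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DIselect)
```

## The problem

Differential-expression analysis of an RNA-seq cohort typically yields
thousands of statistically significant genes — far more than can be
carried into a biomarker panel. DIselect addresses the selection step:
given a samples-by-genes matrix of nonnegative normalized expression
values and a class label per sample (tumor/normal, K cell types, ...),
produce a *ranking* of genes by their power to discriminate the classes,
so that a small panel can be read off the top of the list.

## The model

A one-layer softmax regression maps an expression vector
$x \in \mathbb{R}^J$ to class probabilities

$$P(\text{class } k \mid x) \;=\;
  \frac{\exp(\theta_k^{\mathsf T} x + b_k)}
       {\sum_{l=1}^{K} \exp(\theta_l^{\mathsf T} x + b_l)},$$

with one weight vector $\theta_k \in \mathbb{R}^J$ per class. After
training, let $\hat X^k$ be the class-k average expression profile and

$$WX^k_j = \theta^k_j \,\hat X^k_j .$$

The **Discriminative Index** of gene $j$ sums absolute differences of
these products over all unordered class pairs:

$$DI_j \;=\; \sum_{k_1 < k_2} \bigl|\,WX^{k_1}_j - WX^{k_2}_j\,\bigr|,$$

i.e. $K(K-1)/2$ terms per gene — three at $K = 3$, a single absolute
difference at $K = 2$. A gene scores highly when its trained weight and
its class-average expression jointly differ between classes; a gene with
identical products across classes contributes nothing. Scores are
nonnegative by construction and scale linearly with the weights, so DI
magnitudes are only meaningful relative to one another within one run —
which is all a ranking needs.

The per-feature product is the only reading under which the index is a
$J$-vector: a scalar inner product $\theta_k^{\mathsf T}\hat X^k$ could
not be resolved per gene. The trained bias $b_k$ (on by default, helpful
on unscaled expression) is likewise excluded from $WX$ because DI is
defined per gene.

### Averaging over initializations

Trained weights of a one-layer network depend appreciably on their random
initial values, and so does a single run's DI vector. `rankGenes`
therefore repeats the pipeline `nIter` times, re-initializing with seed
`seed + i` at iteration $i$, and ranks genes by the per-gene *mean* DI.
The reference setting is `nIter = 10000`; rankings on desk-scale problems
are already stable at 50–100 iterations, and the command-line tool
defaults to 100. Each iteration re-initializes weights only; an optional
`resplitFraction` argument additionally re-subsamples the cohort each
iteration for users who want the average to marginalize over splits as
well.

## Training choices

The original method specifies the model but not the optimizer, so the
trainer here is deliberately plain and fully reproducible:

| parameter | default | meaning |
|---|---|---|
| `epochs` | 100 | full-batch gradient steps |
| `learningRate` | 0.01 | step size |
| `clipNorm` | 1 | max global gradient norm per step |
| `l2` | 0 | L2 penalty on weights |
| `initScale` | 1 | init range is `initScale`/√J, zero-mean uniform |
| `useBias` | TRUE | per-class intercept (excluded from DI) |
| `standardize` | `"none"` | per-gene transform (`log2p1`, `minmax` available) |

Gradient clipping, not a tuned learning rate, is what keeps full-batch
descent stable on raw expression scales (values in the hundreds produce
saturated logits from the first epoch; the clipped step then behaves like
a perceptron update and converges on separable directions). The softmax
itself is computed with max-subtraction, so scores of magnitude $10^4$
and beyond cannot overflow. Training aborts with an error naming the
learning rate if the loss ever becomes non-finite, and records first- and
final-epoch losses in the fitted object.

`standardize = "none"` is the default because the intended inputs are
already normalized expression tables, and because DI deliberately
inherits the expression scale: a highly expressed gene with a modest
relative change can outrank a lowly expressed gene with a large fold
change. Users who consider that undesirable should rank on
`log2p1`-transformed data; the transform is applied identically to
training and to the class means so weights and profiles stay on one
scale. The `minmax` mode rescales each gene to $[0,1]$ within the given
matrix; it is *not* anchored to training-set ranges when predicting on
new data, which is a known limitation — use it for ranking, not for
cross-cohort classification.

One deliberate refinement: initial weights are drawn per gene from a
stream keyed by a hash of the gene identifier mixed with the seed, rather
than from one sequential stream. The distribution is unchanged, but the
pipeline becomes exactly equivariant under gene-column permutations and
exactly invariant under sample permutations — properties the test suite
asserts bitwise, and which a positional draw cannot satisfy.

Ties in the final ordering (e.g. two all-zero genes) are broken by
ascending gene identifier in the C locale, so output files are
byte-stable across platforms.

## Evaluation procedures

**Stratified splits.** `stratifiedSplit` partitions samples while
preserving each class's proportions: within a class, every partition
except a designated remainder partition (default: the second, i.e. the
validation set of a train/validation/test split) receives
`round(fraction × n_class)` samples, the remainder partition absorbing
the leftovers. Nearest-integer rounding is what reproduces the canonical
64/16/20 decomposition of a 1,257 + 3,256 cohort into 2,888/723/902;
flooring every partition would give 2,887/724/902.

**Classification of reduced gene sets.** `trainAndScore` restricts the
matrices to a chosen gene list and fits either a gradient-boosted tree
ensemble (xgboost; depth 3, shrinkage 0.3, 50 rounds, single-threaded and
seeded) or the package's own softmax model. Accuracy is the plain
fraction correct — *not* balanced accuracy — so on a 90/10 cohort a
majority-class predictor already scores 0.9; interpret accordingly, and
use `aucScore` when a threshold-free view is wanted. `topkAccuracyCurve`
sweeps the panel size k and exposes where accuracy saturates;
`loocvAccuracy` performs exactly N single-holdout fits and returns the
fold count so the invariant is checkable.

**Ranking overlap.** `rankingOverlap` compares two rankings (either
produced here or imported from an external tool such as a
differential-expression pipeline) as the percentage of shared genes among
their top-d lists, reported to one decimal with half-away-from-zero
rounding computed on an exact tenths scale — 379 shared of 2,000 is
18.95 and prints as 19.0, immune to binary floating-point
representation.

## The synthetic generator

`simulateExpression` emulates the structure the ranking problem actually
presents: thousands of genes, tens-to-hundreds of samples, imbalanced
classes, and a small planted subset of discriminative genes. Defaults are
chosen once to be realistic for normalized bulk RNA-seq and are the
conditions under which the package's guarantees are tested:

* per-gene baseline means lognormal around 100 (log-sd 0.5), the scale of
  RSEM-normalized counts;
* within-gene lognormal noise with log-sd 0.5 (within-class SD ≈ 0.53 ×
  mean), with gamma and negative-binomial alternatives parameterized to
  the same mean;
* default imbalance 180 "cancer" vs 20 "normal" (the ~90/10 ratio of
  tumor/normal compendia);
* planted genes receive an *additive* mean shift in expression units —
  DI depends on absolute magnitudes, so effect sizes are expressed in the
  same units — with +500 on the cancer class as the default strong
  effect (~9 within-class SDs at a baseline mean of 100).

What the generator does **not** model: gene–gene correlation, batch
effects, library-size drift, or single-cell dropout. Passing the planted
recovery suite therefore demonstrates that the estimator does what it
claims under clean strong signal; it does not certify performance on real
cohorts with correlated confounders.

## Problem sizes used in the checks

The recovery guarantee is exercised at J = 500 genes, N = 100 + 100
samples, 5 planted genes at the +500 default shift, 50 averaging
iterations, over 20 generator seeds — sizes at which the full suite runs
comfortably on a laptop while leaving the effect strong enough that a
correct implementation recovers all planted genes essentially always
(the acceptance threshold is ≥ 95% of seeds). Unit tests use cohorts of
tens of samples and tens of genes.

## Degenerate inputs and edge rules

* Constant-zero genes get $WX^k_j = 0$ for every class, hence $DI_j = 0$;
  no special-casing.
* Missing cells in input tables are an error naming the row and column;
  zero-filling is opt-in (`missing = "zero"`). Duplicate gene or sample
  identifiers are always errors — silent deduplication could merge
  distinct loci.
* A class emptied by subsetting, a singleton class under LOOCV, a split
  requested with more partitions than a class has samples: all hard
  errors.

## Known limitations

* DI is a linear, first-order score: genes discriminative only through
  interactions or nonlinear effects will be under-ranked.
* Plain accuracy on imbalanced cohorts flatters weak classifiers (see
  above).
* The 10,000-iteration reference setting is expensive in R at
  genome scale; the implementation is vectorized full-batch BLAS, but
  users ranking 20,000 genes on thousands of samples should expect to
  reduce `nIter` or budget accordingly.
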