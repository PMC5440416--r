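---
title: "Counter-propagation neural networks in cpannr: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counter-propagation neural networks in cpannr: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpannr)
```

## The model

A counter-propagation artificial neural network (CPANN) is an `nx × ny`
grid of neurons carrying two weight blocks: a Kohonen block with one weight
per descriptor and an output (Grossberg) block with one weight per target.
The grid is planar by default; with `toroid = TRUE` opposite edges are
glued so every neuron has the full complement of neighbours.

**Winner selection.**  For an object `x`, the *central neuron* minimizes
the Euclidean distance between `x` and the neuron's Kohonen weights,
restricted to the active descriptor mask.  Exact distance ties are broken
deterministically towards the lowest linear index (row-major: `x` varies
fastest, `index = (y-1)·nx + x`, positions 1-based), so retraining and
prediction are reproducible to the byte.  With
`best_match = "full_vector"` training also includes the output block and
the (non-missing) target values in the distance; prediction always matches
on the Kohonen block alone, because a query's targets are what we are
trying to estimate.

**Prediction** is the exact copy of the central neuron's output weights —
there is no interpolation, which is what makes every prediction traceable
to a specific grid cell and its training occupants.

## Training schedules

Objects are presented in file order, once per epoch, for `epochs` epochs.
After each presentation every neuron within the current radius of the
winner is updated by

```
w ← w + η(t) · a(ring) · (value − w)
```

with the following conventions:

* **Learning rate** `η(t)` decays linearly from `lr_max` to `lr_min` over
  all `epochs × n` global steps (first step exactly `lr_max`, last exactly
  `lr_min`).
* **Radius** shrinks linearly from `max_radius` at the first epoch to 0 at
  the last, computed per epoch and floored to an integer.  Several
  equally defensible discretizations exist; we chose
  `floor(max_radius · (epochs − e) / (epochs − 1))` because it guarantees
  the first epoch uses the full radius and the last updates only the
  winner.  With `epochs = 1` the schedule is degenerate; we define the
  radius as 0 there, i.e. a single winner-only pass.
* **Neighbourhood** is triangular, `a(ring) = max(0, 1 − ring/(radius+1))`
  on Chebyshev square rings, so the winner itself always updates with
  factor 1 and the factor reaches 0 just outside the current radius.
* **Missing targets** (`NA`) skip the output-block update for that target
  while still organizing the Kohonen block, so untested compounds can
  shape the map.

Initial weights are drawn uniformly per column from the empirical range of
the training data (a fixed `[0, 1]` for the bare `cpann_init()`), seeded
by `config$seed`; the caller's RNG state is saved and restored around
every seeded computation.

## Normalization

`fit_normalizer()` implements column standardization
`(x − mean) / sd` fitted on the training set only; targets are never
touched.  The default denominator is the sample standard deviation
(`n − 1`), switchable to `n` for compatibility with population-variance
conventions.  A constant descriptor column is an error — it carries no
information and would divide by zero.  Applying a normalizer to data whose
column count differs is an error; a pure name mismatch proceeds in column
order with a warning, since files from other tools often rename columns.

## Validation

* **LOO** holds out each object once; the per-fold model uses seed
  `config$seed + fold`, so folds are independent but the whole procedure
  is reproducible.
* **LMO** splits the objects, in their file order, into `n_groups`
  contiguous blocks whose sizes differ by at most one.  Contiguity is
  deliberate: datasets are often ordered by compound family, and
  contiguous blocks make LMO a harsher, more honest test than random
  splits.  At `n_groups = n` LMO reduces exactly to LOO.
* **Repeated LMO** re-shuffles the object order before each repetition
  (repetition seed derived from the shuffle seed) and pools the held-out
  predictions.
* **Y-scrambling** permutes the target rows against the descriptor rows
  and re-runs an inner validation; a model whose scrambled `r_cv`
  approaches the real one is fitting noise.  The inner loop defaults to
  LOO as the strictest choice, with LMO available for large sets.

## Applicability domain

The limiting distance is `mean + k·sd` (default `k = 1`) of the pooled
Euclidean distances between the reference objects and their central
neurons; several reference sets may be pooled.  A prediction is in-domain
when its distance is less than *or equal to* the limit — the boundary
object that defines the limit should not be excluded by it.  A manual
limit can be supplied via `ad_threshold()`.

## Read-across

`find_analogues()` collects, for a located query, all objects on rings
`0 … max_ring` around its neuron, excluding the query itself, every object
of the query's own dataset, and analogues without experimental values.
Analogues are ordered by (ring, descriptor distance to the query, id) —
topological closeness first, then geometric, then a deterministic
tie-break.  Three strategies turn analogues into a prediction:
`nearest_analogue` (first analogue's value), `analogue_mean` (arithmetic
mean), and `local_trend` (ordinary least squares of the value on a
user-chosen covariate, evaluated at the query's covariate value — at least
two distinct covariate values required).  The batch `read_across()` drives
this for a whole prediction set and accepts an `overrides` map (query id →
analogue id) to replay manually curated analogue choices;
`compare_model_vs_readacross()` reports both RMSEs over the objects where
read-across was possible, with optional exclusions.

## The synthetic generator

`generate_clustered()` draws Gaussian descriptor clusters whose centres
are rejected until every pairwise distance is at least `separation`
within-cluster standard deviations, with cluster-specific target means.
This is the structure under which the CPANN locality assumption — similar
objects excite nearby neurons and share similar property values — holds by
construction, so it serves as a positive control: a 3×3 map on two
clusters separated by 10 sd recovers the cluster structure with disjoint
neuron sets and a test RMSE well under the target noise floor.  Its
limitations are equally deliberate: real descriptor spaces are not
isotropic Gaussian blobs, targets are rarely piecewise-constant per
cluster, and the generator says nothing about extrapolation — which is why
the applicability-domain machinery is exercised separately.

Typical problem sizes used in the tests: 8–40 objects, 2–5 descriptors,
grids from 1×1 to 9×9, 10–800 epochs.  Published applications use, e.g.,
9×9 planar grids with a triangular neighbourhood, radius 9, learning rate
0.47 → 0.04 and 161 epochs on a few dozen compounds.

## File formats

Datasets are delimited text (tab, comma, semicolon or space) with an `ID`
column, an optional `class` column, target columns marked by the `tar.`
prefix, and all remaining columns as descriptors; `NA` marks missing
targets.  Models are written in a versioned plain-text dialect
(`CPANNR-MODEL 1`): tab-separated header records, optional normalization
records, the variable names, then the Kohonen and output weight rows at
full `%.17g` precision, so a write/read cycle reproduces the model — and
its predictions — exactly.
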