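# cpannr

Counter-propagation artificial neural networks (CPANN) for quantitative
structure–activity modelling, with a complete read-across workflow built on
top of the trained map.

## The model

A CPANN couples a Kohonen self-organizing map with a supervised output
layer.  The Kohonen layer is an `nx × ny` grid of neurons, each holding one
weight per descriptor; the output layer holds, for the same neurons, one
weight per target property.  For an input object the *central* (winning)
neuron is the one whose Kohonen weights are closest in Euclidean distance;
the prediction is simply that neuron's output weights.

Training presents the objects in file order for a fixed number of epochs.
After each presentation, the weights of every neuron within the current
topological radius of the winner move towards the object:

```
w ← w + η(t) · a(ring) · (value − w)
```

where `η(t)` decays linearly from `lr_max` to `lr_min` over all steps,
`a(ring) = max(0, 1 − ring/(radius+1))` is the triangular neighbourhood
function on Chebyshev square rings (with optional toroidal wrap-around),
and the radius shrinks linearly from `max_radius` to 0 over the epochs.
Both layers are updated, so descriptors organize the map while targets are
"dragged along": objects that excite the same or nearby neurons are similar
both structurally and in the modelled property.  That locality is what the
read-across workflow exploits — for a query compound it collects the
*analogues* sitting on the same neuron (ring 0) or on surrounding rings,
and predicts from their experimental values (nearest analogue, analogue
mean, or a local linear trend on a user-chosen covariate).

The package also provides:

* Eq.-style column standardization fitted on the training set only
  (`fit_normalizer()` / `apply_normalizer()`), optionally embedded in the
  model.
* Validation: leave-one-out, leave-many-out (contiguous near-equal blocks),
  repeated LMO with per-repetition shuffles, and Y-scrambling
  (`loo_cv()`, `lmo_cv()`, `repeated_lmo()`, `y_scrambling()`).
* A distance-based applicability domain: the limiting distance is
  `mean + k·sd` of the reference objects' distances to their central
  neurons, boundary-inclusive (`compute_limiting_distance()`,
  `flag_in_domain()`).
* Maps: level plots of single weights, top-maps of object assignments,
  Euclidean and continuous-Tanimoto neuron-similarity maps, text and PNG
  rendering, and a browsable `graphview.html` export with 2D structure
  depiction when ChemmineR is available.
* Plain-text, full-precision model files that round-trip exactly, a simple
  tabular dataset dialect, SMILES maps, a command-line interface
  (`exec/cpannr`), and a seeded clustered-fixture generator
  (`generate_clustered()`).

## Worked example

```r
library(cpannr)

ds    <- generate_clustered(n_clusters = 2, per_cluster = 10, seed = 1)
sets  <- generate_split(ds, c(0.6, 0.4, 0))
model <- cpann(sets$train,
               cpann_config(seed = 2, nx = 3, ny = 3, max_radius = 2,
                            epochs = 40),
               normalize = TRUE)
model
#> CPANN model: 3x3 planar grid, 5 descriptors, 1 target(s)
#>   embedded normalization factors

pred <- predict(model, sets$test, normalize = TRUE)
pred$summary
#>   target n      rmse         r
#> 1  tar.1 8 0.1085612 0.9906253
```

The top-map shows the two clusters settling on opposite sides of the grid:

```r
norm_sets <- lapply(sets[1:2], function(s) apply_normalizer(model$normalizer, s))
preds     <- lapply(norm_sets, function(s) predict(model, s))
tm        <- build_topmap(preds)
writeLines(render_topmap_text(tm, "classes"))
#> C2,C2,C2,C2,C2|.             |C1,C1
#> C2            |.             |C1,C1,C1,C1
#> C2,C2,C2,C2   |.             |C1,C1,C1,C1
```

Read-across from the neighbouring training analogues is competitive with
the network's own prediction:

```r
ra  <- read_across(preds$test, tm, norm_sets, max_ring = 1)
cmp <- compare_model_vs_readacross(ra)
#> model RMSE 0.109  read-across RMSE 0.113  (8 of 8 at ring 0)
```

Cross-validation and the applicability domain:

```r
cv <- lmo_cv(sets$train, cpann_config(seed = 2, nx = 3, ny = 3,
                                      max_radius = 2, epochs = 40), 4)
#> LMO (4 groups): RMSEcv 0.097, Rcv 0.977

ad <- compute_limiting_distance(model,
        apply_normalizer(model$normalizer, sets$train), k_sd = 1)
p  <- predict(model, sets$test, normalize = TRUE, ad = ad)
table(p$table$in_domain)
#> FALSE  TRUE
#>     5     3
```

The CLI covers the same ground:

```sh
exec/cpannr train --data train.txt --normalize --model-out model.unw
exec/cpannr predict --model model.unw --data test.txt --normalize
exec/cpannr readacross --model model.unw --query ext.txt --reference train.txt
```

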