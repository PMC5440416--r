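#' Root-mean-square error
#' @param pred,exp numeric vectors of equal length; pairs with a missing
#'   experimental value must be removed beforehand.
#' @return `sqrt(mean((pred - exp)^2))`.
#' @export
rmse <- function(pred, exp) {
  if (length(pred) != length(exp))
    stop("pred and exp must have equal length", call. = FALSE)
  ok <- !is.na(pred) & !is.na(exp)
  if (!any(ok)) stop("no complete pairs for RMSE", call. = FALSE)
  sqrt(mean((pred[ok] - exp[ok])^2))
}

#' Pearson correlation between experimental and predicted values
#' @inheritParams rmse
#' @export
pearson_r <- function(pred, exp) {
  ok <- !is.na(pred) & !is.na(exp)
  if (sum(ok) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(pred[ok]) == 0 || stats::sd(exp[ok]) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(pred[ok], exp[ok])
}

# row subset of a dataset, order preserved
subset_dataset <- function(ds, idx, name = ds$name) {
  cpann_dataset(ids = ds$ids[idx],
                descriptors = ds$descriptors[idx, , drop = FALSE],
                targets = if (ncol(ds$targets))
                  ds$targets[idx, , drop = FALSE] else NULL,
                classes = ds$classes[idx],
                name = name)
}

#' @export
`[.cpann_dataset` <- function(x, i, ...) subset_dataset(x, i)

# contiguous fold assignment: n objects into g blocks with sizes differing
# by at most one (earlier blocks take the remainder)
fold_assignment <- function(n, g) {
  sizes <- rep(n %/% g, g) + (seq_len(g) <= n %% g)
  rep(seq_len(g), times = sizes)
}

cv_run <- function(train, config, folds, scheme) {
  validate_cpann_dataset(train)
  n <- n_objects(train)
  m <- ncol(train$targets)
  if (!m) stop("cross-validation needs at least one target", call. = FALSE)
  pred <- matrix(NA_real_, n, m)
  g <- max(folds)
  for (f in seq_len(g)) {
    hold <- which(folds == f)
    keep <- which(folds != f)
    cfg_f <- config
    cfg_f$seed <- config$seed + f  # deterministic per-fold seed
    model <- cpann(subset_dataset(train, keep), cfg_f)
    p <- suppressWarnings(predict(model, subset_dataset(train, hold)))
    for (j in seq_len(m))
      pred[hold, j] <- p$table[[paste0("pred.", j)]]
  }
  summ <- data.frame(target = train$target_names, n = NA_integer_,
                     rmse_cv = NA_real_, r_cv = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    ok <- !is.na(train$targets[, j])
    summ$n[j] <- sum(ok)
    summ$rmse_cv[j] <- rmse(pred[ok, j], train$targets[ok, j])
    summ$r_cv[j] <- tryCatch(pearson_r(pred[ok, j], train$targets[ok, j]),
                             error = function(e) NA_real_)
  }
  tab <- data.frame(id = train$ids, fold = folds, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    tab[[paste0("pred.", j)]] <- pred[, j]
    tab[[paste0("exp.", j)]] <- train$targets[, j]
  }
  structure(list(scheme = scheme, table = tab, summary = summ,
                 rmse_cv = summ$rmse_cv[1], r_cv = summ$r_cv[1]),
            class = "cpann_cv")
}

#' @export
print.cpann_cv <- function(x, ...) {
  cat("CPANN cross-validation (", x$scheme$mode, "): ", sep = "")
  cat(sprintf("RMSEcv = %.4f, Rcv = %.4f (n = %d)\n",
              x$rmse_cv, x$r_cv, x$summary$n[1]))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Trains `n` models, each with one object held out, preserving the initial
#' object order; the held-out object is predicted by its model.  Per-fold
#' training seeds derive deterministically from the configuration seed
#' (seed + fold index) so whole runs are reproducible.
#'
#' @param train a [cpann_dataset()] with `n >= 2` and at least one target.
#' @param config a [cpann_config()].
#' @return a `cpann_cv` with the out-of-fold table, `rmse_cv` and `r_cv`.
#' @export
loo_cv <- function(train, config) {
  n <- n_objects(train)
  if (n < 2) stop("leave-one-out needs at least 2 objects", call. = FALSE)
  cv_run(train, config, seq_len(n),
         scheme = list(mode = "loo", groups = n, repeats = 1,
                       seed = config$seed))
}

#' Leave-many-out cross-validation
#'
#' Objects are partitioned into `n_groups` contiguous blocks in their
#' initial order (block sizes differing by at most one); each block is held
#' out once.  `n_groups = n` reduces to [loo_cv()].
#'
#' @inheritParams loo_cv
#' @param n_groups number of blocks, between 2 and `n`.
#' @export
lmo_cv <- function(train, config, n_groups) {
  n <- n_objects(train)
  if (n_groups < 2 || n_groups > n)
    stop("n_groups must be between 2 and the number of objects",
         call. = FALSE)
  cv_run(train, config, fold_assignment(n, n_groups),
         scheme = list(mode = "lmo", groups = n_groups, repeats = 1,
                       seed = config$seed))
}

#' Repeated leave-many-out cross-validation
#'
#' Before each repetition the objects are shuffled with the seeded RNG, then
#' leave-many-out cross-validation runs on the shuffled order.  Per-object
#' out-of-fold predictions are pooled over repetitions.
#'
#' @inheritParams lmo_cv
#' @param n_repeats number of repetitions (>= 1).
#' @param shuffle_seed seed for the shuffles; `NA` disables shuffling
#'   (identity permutation, so one repetition equals [lmo_cv()]).
#' @return a `cpann_cv` whose table carries a `repetition` column;
#'   `per_repetition` holds one summary row per repetition and the pooled
#'   `rmse_cv`/`r_cv` cover all out-of-fold pairs.
#' @export
repeated_lmo <- function(train, config, n_groups, n_repeats = 10,
                         shuffle_seed = config$seed) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  n <- n_objects(train)
  perms <- if (is.na(shuffle_seed)) {
    replicate(n_repeats, seq_len(n), simplify = FALSE)
  } else {
    with_seed(shuffle_seed,
              replicate(n_repeats, sample.int(n), simplify = FALSE))
  }
  runs <- lapply(seq_len(n_repeats), function(r) {
    cfg_r <- config
    cfg_r$seed <- config$seed + (r - 1) * (n_groups + 1)
    cv <- lmo_cv(subset_dataset(train, perms[[r]]), cfg_r, n_groups)
    cv$table$repetition <- r
    cv
  })
  tab <- do.call(rbind, lapply(runs, `[[`, "table"))
  per_rep <- data.frame(repetition = seq_len(n_repeats),
                        rmse_cv = vapply(runs, `[[`, numeric(1), "rmse_cv"),
                        r_cv = vapply(runs, `[[`, numeric(1), "r_cv"))
  m <- ncol(train$targets)
  summ <- data.frame(target = train$target_names, n = NA_integer_,
                     rmse_cv = NA_real_, r_cv = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    p <- tab[[paste0("pred.", j)]]; e <- tab[[paste0("exp.", j)]]
    ok <- !is.na(e)
    summ$n[j] <- sum(ok)
    summ$rmse_cv[j] <- rmse(p[ok], e[ok])
    summ$r_cv[j] <- tryCatch(pearson_r(p[ok], e[ok]),
                             error = function(e) NA_real_)
  }
  structure(list(scheme = list(mode = "repeated_lmo", groups = n_groups,
                               repeats = n_repeats, seed = shuffle_seed),
                 table = tab, summary = summ, per_repetition = per_rep,
                 rmse_cv = summ$rmse_cv[1], r_cv = summ$r_cv[1]),
            class = "cpann_cv")
}

#' Y-scrambling
#'
#' Re-validates the model after randomly permuting the target values
#' (descriptors untouched).  A sound model degrades sharply: the scrambled
#' cross-validated correlation should fall well below the unscrambled
#' reference.
#'
#' @inheritParams loo_cv
#' @param n_repeats number of scrambled repetitions.
#' @param seed seed for the target permutations.
#' @param inner inner validation scheme, `"loo"` (default) or `"lmo"`.
#' @param n_groups groups for `inner = "lmo"`.
#' @return list with `reference` (the unscrambled `cpann_cv`) and
#'   `scrambled`, a data frame of per-repetition `rmse_cv` and `r_cv`.
#' @export
y_scrambling <- function(train, config, n_repeats = 10, seed = config$seed,
                         inner = c("loo", "lmo"), n_groups = NULL) {
  inner <- match.arg(inner)
  n <- n_objects(train)
  if (n < 3) stop("Y-scrambling needs at least 3 objects", call. = FALSE)
  run_cv <- function(ds) {
    if (inner == "loo") loo_cv(ds, config)
    else lmo_cv(ds, config, n_groups)
  }
  reference <- run_cv(train)
  perms <- with_seed(seed,
                     replicate(n_repeats, sample.int(n), simplify = FALSE))
  recs <- lapply(seq_len(n_repeats), function(r) {
    ds <- train
    ds$targets <- ds$targets[perms[[r]], , drop = FALSE]
    cv <- run_cv(ds)
    data.frame(repetition = r, rmse_cv = cv$rmse_cv, r_cv = cv$r_cv)
  })
  list(reference = reference, scrambled = do.call(rbind, recs))
}

#' Applicability-domain threshold
#'
#' Objects whose Euclidean distance to their central neuron is smaller than
#' or equal to the limiting distance are inside the applicability domain
#' (boundary inclusive).  The threshold is either computed from reference
#' datasets with [compute_limiting_distance()] or entered manually here.
#'
#' @param limiting_distance the limiting Euclidean distance (>= 0, finite).
#' @param source `"user_supplied"` or `"computed_from_datasets"`.
#' @param reference names of the datasets the threshold was computed from.
#' @export
ad_threshold <- function(limiting_distance, source = "user_supplied",
                         reference = character(0)) {
  if (!is.finite(limiting_distance) || limiting_distance < 0)
    stop("limiting distance must be finite and >= 0", call. = FALSE)
  structure(list(limiting_distance = limiting_distance, source = source,
                 reference = reference),
            class = "cpann_ad")
}

#' @export
print.cpann_ad <- function(x, ...) {
  cat(sprintf("Applicability domain: limiting distance %.6g (%s)\n",
              x$limiting_distance, x$source))
  invisible(x)
}

#' Compute the limiting Euclidean distance from reference datasets
#'
#' Pools the distances of all reference objects to their central neurons and
#' sets the limit to `mean + k_sd * sd` of that pool.
#'
#' @param model a trained [cpann()] model.
#' @param reference a [cpann_dataset()] or list of them (typically the
#'   training and internal test sets).
#' @param k_sd multiplier on the pooled standard deviation (default 1).
#' @param mask descriptor mask used for the winner search.
#' @return an [ad_threshold()] with `source = "computed_from_datasets"`.
#' @export
compute_limiting_distance <- function(model, reference, k_sd = 1,
                                      mask = NULL) {
  if (inherits(reference, "cpann_dataset")) reference <- list(reference)
  if (!length(reference)) stop("no reference datasets given", call. = FALSE)
  pool <- unlist(lapply(reference, function(ds) {
    suppressWarnings(predict(model, ds, mask = mask))$table$distance
  }))
  if (!length(pool)) stop("reference pool is empty", call. = FALSE)
  s <- if (length(pool) > 1) stats::sd(pool) else 0
  ad_threshold(mean(pool) + k_sd * s, source = "computed_from_datasets",
               reference = vapply(reference, `[[`, character(1), "name"))
}

#' Flag predictions as inside or outside the applicability domain
#'
#' @param prediction a `cpann_prediction` from [predict.cpann()].
#' @param threshold an [ad_threshold()].
#' @return the prediction with `in_domain` set (`distance <= limit`,
#'   boundary inclusive).
#' @export
flag_in_domain <- function(prediction, threshold) {
  prediction$table$in_domain <-
    prediction$table$distance <= threshold$limiting_distance
  prediction$ad <- threshold
  prediction
}
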