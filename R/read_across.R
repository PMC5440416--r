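#' Find structural analogues of a query compound on the top-map
#'
#' Collects, from the reference datasets (those with experimental values —
#' typically training and internal test), the objects sitting on the query's
#' neuron (ring 0) and on neighbouring neurons out to `max_ring`.  The query
#' itself and all other objects of the query's dataset are excluded, as are
#' analogues lacking an experimental value for the chosen target.  The list
#' is ordered by (ring, descriptor Euclidean distance to the query, id) —
#' a total, deterministic order.
#'
#' @param topmap a [build_topmap()] over the reference and query datasets.
#' @param datasets named list of the [cpann_dataset()]s on the map (names
#'   must match the dataset names used for the predictions).
#' @param query_id identifier of the query compound.
#' @param query_dataset name of the dataset holding the query.
#' @param max_ring furthest ring searched (0 = same neuron only; default 1).
#' @param reference names of the datasets analogues may come from; default:
#'   every mapped dataset except the query's.
#' @param target target index whose experimental value the analogue must
#'   carry.
#' @return data frame of analogues with columns dataset, id, class, ring,
#'   descriptor_distance and `exp` (the experimental target value); zero
#'   rows when no analogue exists within `max_ring` (read-across not
#'   possible for this query).
#' @export
find_analogues <- function(topmap, datasets, query_id, query_dataset,
                           max_ring = 1, reference = NULL, target = 1) {
  g <- topmap$geometry
  query_id <- as.character(query_id)
  if (is.null(reference))
    reference <- setdiff(unique(topmap$assignments$dataset), query_dataset)
  qpos <- locate_object(topmap, query_id, dataset = query_dataset)
  qds <- datasets[[query_dataset]]
  if (is.null(qds))
    stop("query dataset '", query_dataset, "' not in `datasets`",
         call. = FALSE)
  qx <- qds$descriptors[match(query_id, qds$ids), ]

  a <- topmap$assignments
  a <- a[a$dataset %in% reference &
           !(a$dataset == query_dataset & a$id == query_id), , drop = FALSE]
  if (!nrow(a)) return(empty_analogues())
  rings <- vapply(seq_len(nrow(a)), function(i) {
    topological_distance(g, qpos, c(a$x[i], a$y[i]))
  }, integer(1))
  keep <- rings <= max_ring
  a <- a[keep, , drop = FALSE]; rings <- rings[keep]
  if (!nrow(a)) return(empty_analogues())

  dd <- numeric(nrow(a)); ev <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    ds <- datasets[[a$dataset[i]]]
    if (is.null(ds))
      stop("dataset '", a$dataset[i], "' not in `datasets`", call. = FALSE)
    row <- match(a$id[i], ds$ids)
    dd[i] <- sqrt(sum((ds$descriptors[row, ] - qx)^2))
    ev[i] <- if (ncol(ds$targets) >= target) ds$targets[row, target]
             else NA_real_
  }
  out <- data.frame(dataset = a$dataset, id = a$id, class = a$class,
                    ring = rings, descriptor_distance = dd, exp = ev,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$exp), , drop = FALSE]
  out <- out[order(out$ring, out$descriptor_distance, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_analogues <- function() {
  data.frame(dataset = character(0), id = character(0), class = character(0),
             ring = integer(0), descriptor_distance = numeric(0),
             exp = numeric(0), stringsAsFactors = FALSE)
}

#' Read-across prediction from an analogue list
#'
#' Strategies: `nearest_analogue` takes the experimental value of the
#' top-ranked analogue; `analogue_mean` averages the analogue values;
#' `local_trend` fits an ordinary least-squares line of the experimental
#' value on a user-supplied covariate (e.g. a substituent count) over the
#' analogues and evaluates it at the query's covariate value.
#'
#' @param analogues a [find_analogues()] data frame (already restricted to
#'   usable analogues).
#' @param strategy one of `"nearest_analogue"`, `"analogue_mean"`,
#'   `"local_trend"`.
#' @param covariate numeric covariate values aligned with the analogue rows
#'   (local trend only).
#' @param at the query's covariate value (local trend only).
#' @param covariate_name label for the covariate.
#' @return a `cpann_readacross` with the prediction, the strategy and the
#'   analogue list.
#' @export
predict_read_across <- function(analogues,
                                strategy = c("nearest_analogue",
                                             "analogue_mean", "local_trend"),
                                covariate = NULL, at = NULL,
                                covariate_name = NULL) {
  strategy <- match.arg(strategy)
  if (!nrow(analogues))
    stop("read-across not possible: no usable analogue", call. = FALSE)
  predicted <- switch(
    strategy,
    nearest_analogue = analogues$exp[1],
    analogue_mean = mean(analogues$exp),
    local_trend = {
      if (nrow(analogues) < 2)
        stop("local trend needs at least 2 analogues", call. = FALSE)
      if (is.null(covariate) || length(covariate) != nrow(analogues))
        stop("local trend needs one covariate value per analogue",
             call. = FALSE)
      if (is.null(at))
        stop("local trend needs the query's covariate value `at`",
             call. = FALSE)
      if (stats::sd(covariate) == 0)
        stop("local trend covariate is constant", call. = FALSE)
      fit <- stats::lm(exp ~ cov,
                       data = data.frame(exp = analogues$exp,
                                         cov = covariate))
      unname(stats::predict(fit, data.frame(cov = at)))
    }
  )
  structure(list(strategy = strategy, analogues = analogues,
                 predicted = predicted, covariate_name = covariate_name),
            class = "cpann_readacross")
}

#' @export
print.cpann_readacross <- function(x, ...) {
  cat(sprintf("read-across (%s): predicted %.4g from %d analogue(s)\n",
              x$strategy, x$predicted, nrow(x$analogues)))
  invisible(x)
}

#' Read-across for every compound of a query set
#'
#' Runs the full workflow for each object of the query prediction set:
#' locate its neuron, collect analogues out to `max_ring`, and predict by
#' the chosen strategy.  The `overrides` mapping (query id to analogue id)
#' replays manual analogue selections; an override pins the chosen analogue
#' regardless of the automatic (ring, distance) ranking, provided it is in
#' the analogue list.
#'
#' @param query_prediction the `cpann_prediction` of the query set (gives
#'   model predictions and neurons).
#' @param topmap a [build_topmap()] over reference and query sets.
#' @param datasets named list of all mapped datasets.
#' @param max_ring furthest ring searched.
#' @param strategy read-across strategy (see [predict_read_across()]).
#' @param target target index.
#' @param overrides optional named character vector, query id -> analogue id.
#' @return a `cpann_readacross_set`: per-query table with columns id, x, y,
#'   possible, ring, analogue_id, analogue_exp, ra_pred, model_pred, exp;
#'   rows where no analogue exists have `possible = FALSE` and `NA`
#'   predictions.
#' @export
read_across <- function(query_prediction, topmap, datasets, max_ring = 1,
                        strategy = "nearest_analogue", target = 1,
                        overrides = NULL) {
  qtab <- query_prediction$table
  qname <- query_prediction$dataset
  pred_col <- paste0("pred.", target)
  exp_col <- paste0("exp.", target)
  rows <- lapply(seq_len(nrow(qtab)), function(i) {
    id <- qtab$id[i]
    an <- find_analogues(topmap, datasets, id, qname,
                         max_ring = max_ring, target = target)
    if (!is.null(overrides) && id %in% names(overrides)) {
      pick <- which(an$id == overrides[[id]])
      if (length(pick))
        an <- rbind(an[pick, , drop = FALSE], an[-pick, , drop = FALSE])
    }
    if (!nrow(an)) {
      return(data.frame(id = id, x = qtab$x[i], y = qtab$y[i],
                        possible = FALSE, ring = NA_integer_,
                        analogue_id = NA_character_,
                        analogue_exp = NA_real_, ra_pred = NA_real_,
                        model_pred = qtab[[pred_col]][i],
                        exp = qtab[[exp_col]][i],
                        stringsAsFactors = FALSE))
    }
    ra <- predict_read_across(an, strategy)
    data.frame(id = id, x = qtab$x[i], y = qtab$y[i], possible = TRUE,
               ring = an$ring[1], analogue_id = an$id[1],
               analogue_exp = an$exp[1], ra_pred = ra$predicted,
               model_pred = qtab[[pred_col]][i], exp = qtab[[exp_col]][i],
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), strategy = strategy,
                 max_ring = max_ring, dataset = qname, target = target),
            class = "cpann_readacross_set")
}

#' @export
print.cpann_readacross_set <- function(x, ...) {
  n_ok <- sum(x$table$possible)
  cat(sprintf("read-across over '%s': possible for %d of %d compounds (%s, max ring %d)\n",
              x$dataset, n_ok, nrow(x$table), x$strategy, x$max_ring))
  invisible(x)
}

#' Compare direct model predictions with read-across predictions
#'
#' Over the compounds for which read-across was possible (minus explicit
#' exclusions), computes the RMSE of the model predictions and of the
#' read-across predictions on the identical compound set, and counts how
#' many read-across predictions used a same-neuron (ring 0) analogue.
#'
#' @param readacross a `cpann_readacross_set` from [read_across()].
#' @param exclusions identifiers excluded from both RMSEs (applied before
#'   either is computed).
#' @return list with `table` (the paired per-object rows used), `n`,
#'   `rmse_model`, `rmse_readacross`, `n_ring0`, `n_readacross`.
#' @export
compare_model_vs_readacross <- function(readacross, exclusions = character(0)) {
  t <- readacross$table
  t <- t[t$possible & !is.na(t$exp), , drop = FALSE]
  n_ra <- nrow(t)
  n_ring0 <- sum(t$ring == 0)
  t <- t[!(t$id %in% as.character(exclusions)), , drop = FALSE]
  if (!nrow(t)) stop("empty comparison set", call. = FALSE)
  list(table = t, n = nrow(t),
       rmse_model = rmse(t$model_pred, t$exp),
       rmse_readacross = rmse(t$ra_pred, t$exp),
       n_ring0 = n_ring0, n_readacross = n_ra)
}
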