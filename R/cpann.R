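#' Training configuration for a CPANN
#'
#' Collects every knob of the training procedure.  The defaults reproduce
#' the settings used for the worked bioconcentration-factor model: a 9x9
#' planar grid, triangular neighbourhood with starting correction radius 9,
#' learning rate decaying from 0.47 to 0.04, 161 epochs, winner chosen on
#' the Kohonen (descriptor) layer only, random seed 1234.
#'
#' @param seed integer RNG seed; the same seed, data and configuration give
#'   a bit-identical trained model.
#' @param nx,ny grid dimensions.
#' @param toroid toroidal boundary conditions.
#' @param neighborhood neighbourhood correction shape; `"triangular"`.
#' @param max_radius furthest neuron for correction: the correction radius
#'   starts here and shrinks linearly to 0 over the epochs.
#' @param lr_max,lr_min maximal and minimal learning rate; the rate decays
#'   linearly over the global step index (epochs x objects).
#' @param best_match `"kohonen_only"` (winner by descriptor distance, the
#'   usual choice) or `"full_vector"` (winner by distance over the
#'   concatenated descriptor+target vector during training; prediction
#'   always uses the Kohonen layer since targets are unknown then).
#' @param epochs number of passes over the training set (>= 1).
#' @return an object of class `cpann_config`.
#' @export
cpann_config <- function(seed = 1234L, nx = 9L, ny = 9L, toroid = FALSE,
                         neighborhood = "triangular", max_radius = 9L,
                         lr_max = 0.47, lr_min = 0.04,
                         best_match = c("kohonen_only", "full_vector"),
                         epochs = 161L) {
  best_match <- match.arg(best_match)
  neighborhood <- match.arg(neighborhood, "triangular")
  if (!(lr_min > 0 && lr_min <= lr_max))
    stop("require 0 < lr_min <= lr_max", call. = FALSE)
  if (max_radius < 0) stop("max_radius must be >= 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(
    list(seed = as.integer(seed),
         geometry = grid_geometry(nx, ny, toroid),
         neighborhood = neighborhood,
         max_radius = as.integer(max_radius),
         lr_max = lr_max, lr_min = lr_min,
         best_match = best_match,
         epochs = as.integer(epochs)),
    class = "cpann_config"
  )
}

#' @export
print.cpann_config <- function(x, ...) {
  cat(sprintf(paste0("CPANN config: %dx%d %s grid, %s neighbourhood, ",
                     "radius %d, lr %.3g->%.3g, %d epochs, best match %s, ",
                     "seed %d\n"),
              x$geometry$nx, x$geometry$ny,
              if (x$geometry$toroid) "toroidal" else "planar",
              x$neighborhood, x$max_radius, x$lr_max, x$lr_min,
              x$epochs, x$best_match, x$seed))
  invisible(x)
}

#' Initialize an untrained CPANN
#'
#' Weights are drawn uniformly, column by column, from the supplied ranges
#' (by default `[0, 1]`; [cpann()] passes the empirical min/max of each
#' training column so first-epoch distances are commensurate with the data).
#' The draw is seeded: the same seed gives bit-identical weight blocks.
#'
#' @param config a [cpann_config()].
#' @param descriptor_names,target_names variable names for the two layers.
#' @param descriptor_ranges,target_ranges optional 2 x k matrices of
#'   (min, max) per column.
#' @return an untrained object of class `cpann`.
#' @export
cpann_init <- function(config, descriptor_names, target_names = character(0),
                       descriptor_ranges = NULL, target_ranges = NULL) {
  g <- config$geometry
  nn <- n_neurons(g)
  k <- length(descriptor_names)
  m <- length(target_names)
  if (k < 1) stop("at least one descriptor is required", call. = FALSE)
  if (is.null(descriptor_ranges))
    descriptor_ranges <- rbind(rep(0, k), rep(1, k))
  if (is.null(target_ranges))
    target_ranges <- rbind(rep(0, max(m, 1)), rep(1, max(m, 1)))[, seq_len(m), drop = FALSE]
  draw <- function(ranges, ncol_) {
    w <- matrix(0, nn, ncol_)
    for (j in seq_len(ncol_))
      w[, j] <- stats::runif(nn, ranges[1, j], ranges[2, j])
    w
  }
  model <- with_seed(config$seed, {
    W <- draw(descriptor_ranges, k)
    O <- draw(target_ranges, m)
    list(W = W, O = O)
  })
  colnames(model$W) <- descriptor_names
  if (m) colnames(model$O) <- target_names
  structure(
    list(geometry = g,
         kohonen = model$W,
         output = model$O,
         descriptor_names = descriptor_names,
         target_names = target_names,
         config = config,
         normalizer = NULL,
         trained = FALSE),
    class = "cpann"
  )
}

# correction radius at a given 1-based epoch: linear shrink from max_radius
# at epoch 1 to 0 at the final epoch (integer floor); a single epoch runs
# at the schedule's end point, radius 0
radius_at_epoch <- function(config, epoch) {
  if (config$epochs == 1) return(0L)
  as.integer(floor(config$max_radius *
                     (config$epochs - epoch) / (config$epochs - 1)))
}

# learning rate at global step t (0-based) out of t_total steps
learning_rate_at <- function(config, t, t_total) {
  if (t_total <= 1) return(config$lr_max)
  config$lr_max - (config$lr_max - config$lr_min) * t / (t_total - 1)
}

#' Fit a counter-propagation neural network
#'
#' Trains a Kohonen self-organizing map coupled to a supervised output
#' (Grossberg) layer.  Each epoch presents the training objects in file
#' order; for each object the winning ("central") neuron is found, and the
#' Kohonen weights of every neuron within the current correction radius move
#' toward the object's descriptors while the output weights move toward its
#' targets, both by `eta(t) * a(ring) * (value - weight)` with the
#' triangular neighbourhood factor `a`.  The learning rate decays linearly
#' from `lr_max` to `lr_min` over all steps and the radius shrinks linearly
#' to zero over the epochs.  Missing target entries are simply not used for
#' the output-layer update of that object.
#'
#' Descriptors are expected on a common scale; pass `normalize = TRUE` to
#' standardize them from this training set (the factors are embedded in the
#' model and saved with it), or standardize beforehand with
#' [fit_normalizer()] / [apply_normalizer()].
#'
#' @param data a [cpann_dataset()] with at least one target column.
#' @param config a [cpann_config()].
#' @param normalize fit a normalizer on `data`, standardize, and embed the
#'   factors in the model.
#' @return a trained object of class `cpann`.
#' @seealso [predict.cpann()], [write_cpann()], [level_plot()]
#' @examples
#' ds <- generate_clustered(seed = 7)
#' m <- cpann(ds, cpann_config(nx = 3, ny = 3, max_radius = 2, epochs = 30),
#'            normalize = TRUE)
#' predict(m, ds, normalize = TRUE)
#' @export
cpann <- function(data, config = cpann_config(), normalize = FALSE) {
  validate_cpann_dataset(data)
  nz <- NULL
  if (normalize) {
    nz <- fit_normalizer(data)
    data <- apply_normalizer(nz, data)
  }
  if (anyNA(data$descriptors) || any(!is.finite(data$descriptors)))
    stop("descriptors must be finite for training", call. = FALSE)
  n <- n_objects(data)
  k <- ncol(data$descriptors)
  m <- ncol(data$targets)

  drange <- apply(data$descriptors, 2, range)
  trange <- if (m) apply(data$targets, 2, function(v) {
    r <- range(v, na.rm = TRUE)
    if (!all(is.finite(r))) c(0, 1) else r
  }) else NULL

  model <- cpann_init(config, data$descriptor_names, data$target_names,
                      descriptor_ranges = drange, target_ranges = trange)
  g <- config$geometry
  nn <- n_neurons(g)
  # ring distance from every neuron to every neuron, computed once
  rings <- matrix(vapply(seq_len(nn), function(i) ring_distances_from(g, i),
                         integer(nn)), nrow = nn, ncol = nn)

  W <- model$kohonen
  O <- model$output
  X <- data$descriptors
  Y <- data$targets
  t_total <- config$epochs * n
  t <- 0L
  for (epoch in seq_len(config$epochs)) {
    radius <- radius_at_epoch(config, epoch)
    for (i in seq_len(n)) {
      eta <- learning_rate_at(config, t, t_total)
      x <- X[i, ]
      win <- winner_index(W, x,
                          O = if (config$best_match == "full_vector") O,
                          y = if (config$best_match == "full_vector") Y[i, ])
      a <- neighborhood_factor(rings[, win], radius)
      fac <- eta * a
      upd <- fac > 0
      W[upd, ] <- W[upd, , drop = FALSE] +
        fac[upd] * (rep(x, each = sum(upd)) -
                      W[upd, , drop = FALSE])
      if (m) {
        y <- Y[i, ]
        ok <- which(!is.na(y))
        if (length(ok))
          O[upd, ok] <- O[upd, ok, drop = FALSE] +
            fac[upd] * (rep(y[ok], each = sum(upd)) -
                          O[upd, ok, drop = FALSE])
      }
      t <- t + 1L
    }
  }
  model$kohonen <- W
  model$output <- O
  model$normalizer <- nz
  model$trained <- TRUE
  model
}

# winning neuron index by squared Euclidean distance; when O and y are
# supplied the distance runs over the concatenated descriptor+target vector
# (NA target components dropped); ties break to the lowest linear index
winner_index <- function(W, x, O = NULL, y = NULL, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(W))
  d2 <- rowSums((W[, cols, drop = FALSE] -
                   rep(x[cols], each = nrow(W)))^2)
  if (!is.null(O) && !is.null(y)) {
    ok <- which(!is.na(y))
    if (length(ok))
      d2 <- d2 + rowSums((O[, ok, drop = FALSE] -
                            rep(y[ok], each = nrow(O)))^2)
  }
  which.min(d2)  # which.min returns the first (lowest index) minimum
}

resolve_mask <- function(model, mask) {
  if (is.null(mask)) return(seq_along(model$descriptor_names))
  if (is.character(mask)) {
    idx <- match(mask, model$descriptor_names)
    if (anyNA(idx))
      stop("unknown descriptor(s) in mask: ",
           paste(mask[is.na(idx)], collapse = ", "), call. = FALSE)
  } else if (is.logical(mask)) {
    idx <- which(mask)
  } else idx <- as.integer(mask)
  if (!length(idx)) stop("descriptor mask must be non-empty", call. = FALSE)
  if (any(idx < 1 | idx > length(model$descriptor_names)))
    stop("mask index out of range", call. = FALSE)
  sort(unique(idx))
}

#' Find the central neuron for a descriptor vector
#'
#' The neuron whose Kohonen weights have the smallest Euclidean distance to
#' the object, computed over the masked descriptor subset.  Ties break
#' deterministically to the lowest linear index (row-major, x fastest).
#'
#' @param model a trained [cpann()] model.
#' @param x numeric descriptor vector of the model's length.
#' @param mask descriptor subset (names, indices or logical); `NULL` = all.
#' @return list with `position` (`c(x, y)`), `distance` (Euclidean, over the
#'   masked descriptors) and `index` (linear neuron index).
#' @export
find_central_neuron <- function(model, x, mask = NULL) {
  cols <- resolve_mask(model, mask)
  if (length(x) != length(model$descriptor_names))
    stop("descriptor vector length mismatch", call. = FALSE)
  idx <- winner_index(model$kohonen, x, cols = cols)
  d <- sqrt(sum((model$kohonen[idx, cols] - x[cols])^2))
  list(position = index_position(model$geometry, idx),
       distance = d, index = idx)
}

#' Predict endpoints with a CPANN model
#'
#' Each object is mapped to its central neuron (winner over the masked
#' descriptors, Kohonen layer only) and the predictions are read directly
#' from the output-layer weights at that position — exact copies, no
#' interpolation.  RMSE and the Pearson correlation between experimental and
#' predicted values are reported per target over the objects whose
#' experimental value is present.
#'
#' @param object a trained [cpann()] model.
#' @param newdata a [cpann_dataset()].
#' @param mask descriptor subset used to locate the central neuron.
#' @param ad optional [ad_threshold()]; when given, each object is flagged
#'   in/out of the applicability domain by its distance to the central
#'   neuron.
#' @param normalize apply the model's embedded normalizer to `newdata`
#'   first (error if the model has none).
#' @param ... unused.
#' @return a `cpann_prediction`: a list with the per-object `table`
#'   (id, class, neuron position, distance, `pred.i`/`exp.i` columns,
#'   `in_domain`), the per-target `summary` (n, rmse, r) and the dataset
#'   name.
#' @export
predict.cpann <- function(object, newdata, mask = NULL, ad = NULL,
                          normalize = FALSE, ...) {
  validate_cpann_dataset(newdata)
  if (normalize) {
    if (is.null(object$normalizer))
      stop("model carries no normalizer", call. = FALSE)
    newdata <- apply_normalizer(object$normalizer, newdata)
  }
  if (ncol(newdata$descriptors) != length(object$descriptor_names))
    stop("descriptor count mismatch between model and dataset", call. = FALSE)
  if (!identical(newdata$descriptor_names, object$descriptor_names))
    warning("variable names in the dataset are not the same as in the ",
            "model; proceeding in column order", call. = FALSE)
  cols <- resolve_mask(object, mask)
  n <- n_objects(newdata)
  m <- length(object$target_names)
  pos <- matrix(NA_integer_, n, 2)
  dist <- numeric(n)
  pred <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    w <- find_central_neuron(object, newdata$descriptors[i, ], mask = cols)
    pos[i, ] <- w$position
    dist[i] <- w$distance
    if (m) pred[i, ] <- object$output[w$index, ]
  }
  tab <- data.frame(id = newdata$ids, class = newdata$classes,
                    x = pos[, 1], y = pos[, 2], distance = dist,
                    stringsAsFactors = FALSE)
  exp_ <- matrix(NA_real_, n, m)
  n_targets_data <- ncol(newdata$targets)
  for (j in seq_len(min(m, n_targets_data))) exp_[, j] <- newdata$targets[, j]
  for (j in seq_len(m)) {
    tab[[paste0("pred.", j)]] <- pred[, j]
    tab[[paste0("exp.", j)]] <- exp_[, j]
  }
  summ <- data.frame(target = object$target_names,
                     n = NA_integer_, rmse = NA_real_, r = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    ok <- !is.na(exp_[, j])
    summ$n[j] <- sum(ok)
    if (any(ok)) summ$rmse[j] <- rmse(pred[ok, j], exp_[ok, j])
    if (sum(ok) >= 2 && stats::sd(exp_[ok, j]) > 0 &&
        stats::sd(pred[ok, j]) > 0)
      summ$r[j] <- pearson_r(pred[ok, j], exp_[ok, j])
  }
  tab$in_domain <- if (!is.null(ad)) dist <= ad$limiting_distance
                   else rep(NA, n)
  structure(list(dataset = newdata$name, geometry = object$geometry,
                 table = tab, summary = summ,
                 target_names = object$target_names),
            class = "cpann_prediction")
}

#' @export
print.cpann_prediction <- function(x, ...) {
  cat(render_prediction_report(x), sep = "\n")
  invisible(x)
}

#' @export
print.cpann <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("CPANN model: %dx%d %s grid, %d descriptors, %d target(s)%s\n",
              g$nx, g$ny, if (g$toroid) "toroidal" else "planar",
              length(x$descriptor_names), length(x$target_names),
              if (x$trained) "" else " (untrained)"))
  if (!is.null(x$normalizer)) cat("  embedded normalization factors\n")
  invisible(x)
}

#' @export
summary.cpann <- function(object, ...) {
  print(object)
  print(object$config)
  if (length(object$target_names)) {
    rng <- apply(object$output, 2, range)
    for (j in seq_along(object$target_names))
      cat(sprintf("  response surface %s: [%.4g, %.4g]\n",
                  object$target_names[j], rng[1, j], rng[2, j]))
  }
  invisible(object)
}

#' Model weights
#' @param object a [cpann()] model.
#' @param ... unused.
#' @return list with the Kohonen and output weight matrices
#'   (neurons x variables, linear neuron order).
#' @export
coef.cpann <- function(object, ...) {
  list(kohonen = object$kohonen, output = object$output)
}

#' Level plot of a model variable
#'
#' Draws the 2D weight surface of one descriptor or target across the grid
#' (for targets this is the response surface).
#'
#' @param x a [cpann()] model.
#' @param variable descriptor or target name (default: first target).
#' @param ... passed to [graphics::image()].
#' @export
plot.cpann <- function(x, variable = NULL, ...) {
  if (is.null(variable))
    variable <- if (length(x$target_names)) x$target_names[1]
                else x$descriptor_names[1]
  grid <- level_plot(x, variable)
  graphics::image(seq_len(nrow(grid)), seq_len(ncol(grid)), grid,
                  xlab = "x", ylab = "y", main = variable,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(grid)
}
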