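#' Weight surface ("level plot") of one variable
#'
#' Returns the grid of one variable's weight at each neuron: the Kohonen
#' level for a descriptor, the response surface for a target.
#'
#' @param model a [cpann()] model.
#' @param variable a descriptor or target name.
#' @return numeric `nx x ny` matrix; element `[x, y]` is the weight of the
#'   neuron at position `(x, y)`.
#' @export
level_plot <- function(model, variable) {
  g <- model$geometry
  if (variable %in% model$descriptor_names) {
    v <- model$kohonen[, match(variable, model$descriptor_names)]
  } else if (variable %in% model$target_names) {
    v <- model$output[, match(variable, model$target_names)]
  } else {
    stop("unknown variable '", variable, "'; valid names: ",
         paste(c(model$descriptor_names, model$target_names),
               collapse = ", "), call. = FALSE)
  }
  matrix(v, nrow = g$nx, ncol = g$ny)  # linear order is x fastest
}

#' Map of Euclidean distances to a reference neuron
#'
#' Per-neuron Euclidean distance between the Kohonen weight vectors of the
#' reference neuron and every neuron on the grid; 0 at the reference.
#'
#' @param model a [cpann()] model.
#' @param ref reference position `c(x, y)`.
#' @return numeric `nx x ny` matrix.
#' @export
euclidean_distance_map <- function(model, ref) {
  g <- model$geometry
  check_on_grid(g, ref)
  w <- model$kohonen[position_index(g, ref), ]
  d <- sqrt(rowSums((model$kohonen - rep(w, each = nrow(model$kohonen)))^2))
  matrix(d, nrow = g$nx, ncol = g$ny)
}

#' Continuous Tanimoto similarity coefficient
#'
#' For real-valued vectors, `T = sum(a*b) / (sum(a^2) + sum(b^2) - sum(a*b))`;
#' 1 when the vectors are identical and nonzero.
#'
#' @param a,b numeric vectors of equal length, not both all-zero.
#' @return the coefficient.
#' @export
continuous_tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  ab <- sum(a * b)
  den <- sum(a^2) + sum(b^2) - ab
  if (den == 0)
    stop("continuous Tanimoto coefficient undefined for two zero vectors",
         call. = FALSE)
  ab / den
}

#' Map of continuous Tanimoto coefficients to a reference neuron
#'
#' Similarity between the reference neuron's Kohonen weight vector and every
#' neuron's; 1 at the reference.  A degenerate all-zero pair (undefined
#' coefficient) is reported as `NaN` rather than an error.
#'
#' @inheritParams euclidean_distance_map
#' @return numeric `nx x ny` matrix, `NaN` where undefined.
#' @export
tanimoto_map <- function(model, ref) {
  g <- model$geometry
  check_on_grid(g, ref)
  w <- model$kohonen[position_index(g, ref), ]
  out <- apply(model$kohonen, 1, function(v) {
    tryCatch(continuous_tanimoto(w, v), error = function(e) NaN)
  })
  matrix(out, nrow = g$nx, ncol = g$ny)
}

#' Build a top-map from predictions
#'
#' The top-map lists, for each neuron, the objects that excited it.  Objects
#' close together on the map are structurally similar — the basis for
#' read-across.
#'
#' @param predictions one `cpann_prediction` or a list of them (e.g.
#'   training, internal test and external sets), all from the same model
#'   geometry.
#' @return a `cpann_topmap`: the grid geometry plus an assignment table with
#'   columns dataset, id, class, x, y.
#' @export
build_topmap <- function(predictions) {
  if (inherits(predictions, "cpann_prediction"))
    predictions <- list(predictions)
  g <- predictions[[1]]$geometry
  for (p in predictions) {
    if (!identical(unclass(p$geometry), unclass(g)))
      stop("predictions come from different grid geometries", call. = FALSE)
  }
  assignments <- do.call(rbind, lapply(predictions, function(p) {
    data.frame(dataset = p$dataset, id = p$table$id, class = p$table$class,
               x = p$table$x, y = p$table$y, stringsAsFactors = FALSE)
  }))
  structure(list(geometry = g, assignments = assignments),
            class = "cpann_topmap")
}

#' @export
print.cpann_topmap <- function(x, ...) {
  cat(sprintf("CPANN top-map (%dx%d): %d objects from %d dataset(s)\n",
              x$geometry$nx, x$geometry$ny, nrow(x$assignments),
              length(unique(x$assignments$dataset))))
  invisible(x)
}

#' Objects occupying one top-map cell
#' @param topmap a [build_topmap()] result.
#' @param pos position `c(x, y)`.
#' @return the assignment rows at that cell.
#' @export
topmap_cell <- function(topmap, pos) {
  check_on_grid(topmap$geometry, pos)
  a <- topmap$assignments
  a[a$x == pos[1] & a$y == pos[2], , drop = FALSE]
}

#' Locate an object on the top-map
#'
#' @param topmap a [build_topmap()] result.
#' @param id object identifier; when the same ID occurs in several datasets,
#'   give `dataset` to disambiguate.
#' @param dataset optional dataset name.
#' @return the position `c(x, y)` of the cell holding the object.
#' @export
locate_object <- function(topmap, id, dataset = NULL) {
  a <- topmap$assignments
  hit <- a$id == as.character(id)
  if (!is.null(dataset)) hit <- hit & a$dataset == dataset
  if (!any(hit))
    stop("object '", id, "' not found on the top-map", call. = FALSE)
  row <- a[which(hit)[1], ]
  c(x = row$x, y = row$y)
}
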