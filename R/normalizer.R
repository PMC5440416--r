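#' Descriptor standardization
#'
#' CPANN training expects descriptors standardized column-wise,
#' `x_norm = (x - x_average) / s`, where the mean and standard deviation are
#' learned from the designated normalization (training) set and then reused
#' unchanged on every later set, so test and external sets never contribute
#' to the factors.  Only descriptors are transformed; targets, IDs and
#' classes pass through untouched.
#'
#' @param ds a [cpann_dataset()] with at least two objects.
#' @param sd_denominator `"n-1"` (sample standard deviation, the default) or
#'   `"n"` (population form).
#' @return a `cpann_normalizer` with fields `descriptor_names`, `means`,
#'   `sds`.
#' @export
fit_normalizer <- function(ds, sd_denominator = c("n-1", "n")) {
  validate_cpann_dataset(ds)
  sd_denominator <- match.arg(sd_denominator)
  n <- n_objects(ds)
  if (n < 2) stop("need at least 2 objects to fit a normalizer", call. = FALSE)
  means <- colMeans(ds$descriptors)
  sds <- apply(ds$descriptors, 2, stats::sd)
  if (sd_denominator == "n") sds <- sds * sqrt((n - 1) / n)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero))
    stop("constant descriptor column(s): ",
         paste(ds$descriptor_names[zero], collapse = ", "),
         " (standard deviation is zero)", call. = FALSE)
  structure(
    list(descriptor_names = ds$descriptor_names,
         means = unname(means), sds = unname(sds)),
    class = "cpann_normalizer"
  )
}

#' @export
print.cpann_normalizer <- function(x, ...) {
  cat("CPANN normalizer for", length(x$descriptor_names), "descriptors\n")
  invisible(x)
}

#' Apply standardization factors to a dataset
#'
#' @param nz a `cpann_normalizer` from [fit_normalizer()].
#' @param ds a [cpann_dataset()] whose descriptors match `nz`; a name
#'   mismatch with matching count produces a warning and the computation
#'   proceeds in column order, mirroring the model-file warning contract.
#' @return the dataset with standardized descriptors.
#' @export
apply_normalizer <- function(nz, ds) {
  validate_cpann_dataset(ds)
  k <- length(nz$descriptor_names)
  if (ncol(ds$descriptors) != k)
    stop("descriptor count mismatch: normalizer has ", k,
         ", dataset has ", ncol(ds$descriptors), call. = FALSE)
  missing <- setdiff(nz$descriptor_names, ds$descriptor_names)
  if (length(missing) && !identical(ds$descriptor_names, nz$descriptor_names))
    warning("descriptor names differ from the normalizer (",
            paste(utils::head(missing, 3), collapse = ", "),
            if (length(missing) > 3) ", ..." else "",
            "); proceeding in column order", call. = FALSE)
  ds$descriptors <- sweep(sweep(ds$descriptors, 2, nz$means, "-"),
                          2, nz$sds, "/")
  ds
}
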