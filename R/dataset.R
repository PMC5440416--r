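#' Compound dataset for CPANN modelling
#'
#' A `cpann_dataset` holds one table of compounds: an identifier and an
#' optional class label per compound, a numeric descriptor matrix and a
#' numeric target (endpoint) matrix.  Target entries may be `NA` for
#' untested compounds; descriptor entries must be complete.
#'
#' @param ids character vector of unique object identifiers.
#' @param descriptors numeric matrix, one row per object, with column names
#'   giving the descriptor names.
#' @param targets numeric matrix (possibly zero columns) of endpoint values,
#'   column names giving the target names; `NA` marks a missing experimental
#'   value.
#' @param classes character vector of class labels (empty string when
#'   unknown).
#' @param name label for the dataset (e.g. "training").
#' @return An object of class `cpann_dataset` with fields `name`, `ids`,
#'   `classes`, `descriptor_names`, `descriptors`, `target_names`, `targets`.
#' @export
cpann_dataset <- function(ids, descriptors, targets = NULL, classes = NULL,
                          name = "dataset") {
  ids <- as.character(ids)
  descriptors <- as.matrix(descriptors)
  storage.mode(descriptors) <- "double"
  if (is.null(targets)) {
    targets <- matrix(numeric(0), nrow = length(ids), ncol = 0)
  }
  targets <- as.matrix(targets)
  storage.mode(targets) <- "double"
  if (is.null(classes)) classes <- rep("", length(ids))
  classes <- as.character(classes)

  ds <- structure(
    list(
      name = as.character(name)[1],
      ids = ids,
      classes = classes,
      descriptor_names = colnames(descriptors),
      descriptors = descriptors,
      target_names = if (ncol(targets)) colnames(targets) else character(0),
      targets = targets
    ),
    class = "cpann_dataset"
  )
  validate_cpann_dataset(ds)
  ds
}

validate_cpann_dataset <- function(ds) {
  n <- length(ds$ids)
  if (anyDuplicated(ds$ids))
    stop("duplicate object IDs: ",
         paste(unique(ds$ids[duplicated(ds$ids)]), collapse = ", "),
         call. = FALSE)
  if (nrow(ds$descriptors) != n || length(ds$classes) != n ||
      nrow(ds$targets) != n)
    stop("row counts of ids, classes, descriptors and targets differ",
         call. = FALSE)
  if (ncol(ds$descriptors) < 1)
    stop("a dataset needs at least one descriptor", call. = FALSE)
  if (is.null(ds$descriptor_names) ||
      anyDuplicated(ds$descriptor_names))
    stop("descriptor columns must carry unique names", call. = FALSE)
  if (length(intersect(ds$descriptor_names, ds$target_names)))
    stop("descriptor and target names must be disjoint", call. = FALSE)
  if (anyNA(ds$descriptors))
    stop("descriptor values must be complete (NA found)", call. = FALSE)
  bad <- grepl("\t|\n", c(ds$descriptor_names, ds$target_names, ds$ids))
  if (any(bad))
    stop("names and IDs must not contain tabs or newlines", call. = FALSE)
  invisible(ds)
}

#' @export
print.cpann_dataset <- function(x, ...) {
  cat("CPANN dataset '", x$name, "': ", length(x$ids), " objects, ",
      ncol(x$descriptors), " descriptors, ", ncol(x$targets), " targets\n",
      sep = "")
  if (length(x$target_names))
    cat("  targets:", paste(x$target_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of objects in a dataset
#' @param x a `cpann_dataset`.
#' @export
n_objects <- function(x) length(x$ids)

delimiter_char <- function(delimiter) {
  switch(match.arg(delimiter, c("tab", "comma", "semicolon", "space")),
         tab = "\t", comma = ",", semicolon = ";", space = " ")
}

# Header grammar: column "ID" is the identifier, optional column "class" is
# the class label, columns starting with "tar." are targets, everything else
# is a descriptor.
TARGET_PREFIX <- "tar."

#' Read a delimited dataset file
#'
#' The first row is a header.  The column named `ID` holds object
#' identifiers, an optional column named `class` holds class labels, columns
#' whose name starts with `tar.` are targets (e.g. `tar.1:logBCF`), and all
#' remaining columns are descriptors.  Missing target values are written as
#' `NA`.
#'
#' @param path file to read.
#' @param delimiter one of `"tab"`, `"comma"`, `"semicolon"`, `"space"`.
#' @param name dataset label; defaults to the file name.
#' @return a [cpann_dataset()].
#' @export
read_dataset <- function(path, delimiter = "tab",
                         name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- delimiter_char(delimiter)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("dataset file needs a header and at least one data row", call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  ncols <- length(header)
  for (i in seq_along(fields)[-1]) {
    if (length(fields[[i]]) != ncols)
      stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                   path, i, length(fields[[i]]), ncols), call. = FALSE)
  }
  body <- do.call(rbind, fields[-1])

  id_col <- which(header == "ID")
  if (length(id_col) != 1)
    stop("header must contain exactly one 'ID' column", call. = FALSE)
  class_col <- which(header == "class")
  tar_cols <- which(startsWith(header, TARGET_PREFIX))
  desc_cols <- setdiff(seq_len(ncols), c(id_col, class_col, tar_cols))
  if (!length(desc_cols))
    stop("no descriptor columns found", call. = FALSE)

  parse_num <- function(cols, role) {
    m <- matrix(NA_real_, nrow(body), length(cols),
                dimnames = list(NULL, header[cols]))
    for (j in seq_along(cols)) {
      raw <- body[, cols[j]]
      v <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(v) & !(raw %in% c("NA", "")))
      if (length(bad) && role == "descriptor")
        stop(sprintf("non-numeric descriptor value '%s' at row %d, column '%s'",
                     raw[bad[1]], bad[1], header[cols[j]]), call. = FALSE)
      if (role == "descriptor" && anyNA(v))
        stop(sprintf("missing descriptor value at row %d, column '%s'",
                     which(is.na(v))[1], header[cols[j]]), call. = FALSE)
      m[, j] <- v
    }
    m
  }

  cpann_dataset(
    ids = body[, id_col],
    descriptors = parse_num(desc_cols, "descriptor"),
    targets = if (length(tar_cols)) parse_num(tar_cols, "target") else NULL,
    classes = if (length(class_col)) body[, class_col[1]] else NULL,
    name = name
  )
}

#' Write a dataset to a delimited text file
#'
#' The file is re-readable by [read_dataset()] with identical content;
#' numeric values are written at full double precision.
#'
#' @param ds a [cpann_dataset()].
#' @param path output file.
#' @param delimiter as in [read_dataset()].
#' @export
write_dataset <- function(ds, path, delimiter = "tab") {
  validate_cpann_dataset(ds)
  sep <- delimiter_char(delimiter)
  header <- c("ID", "class", ds$descriptor_names, ds$target_names)
  rows <- vapply(seq_along(ds$ids), function(i) {
    paste(c(ds$ids[i], ds$classes[i],
            fmt_num(ds$descriptors[i, ]),
            if (ncol(ds$targets)) fmt_num(ds$targets[i, ])),
          collapse = sep)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = sep), rows), con)
  invisible(path)
}

# full-precision decimal rendering that survives as.numeric() round-trip
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read an ID-to-SMILES map
#'
#' Two-column delimited text, identifier then SMILES string.  Lookups of
#' absent identifiers return `NULL` rather than failing.
#'
#' @param path file to read.
#' @param delimiter as in [read_dataset()].
#' @return a named character vector of class `cpann_smiles_map`.
#' @export
read_smiles_map <- function(path, delimiter = "tab") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- delimiter_char(delimiter)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, sep, fixed = TRUE)
  # tolerate a header line labelled ID/SMILES
  if (length(fields) && identical(toupper(fields[[1]][1]), "ID"))
    fields <- fields[-1]
  ok <- vapply(fields, length, integer(1)) >= 2
  if (!all(ok))
    stop("SMILES map rows need two columns (line ",
         which(!ok)[1], ")", call. = FALSE)
  ids <- vapply(fields, `[`, character(1), 1)
  smi <- vapply(fields, `[`, character(1), 2)
  if (anyDuplicated(ids))
    stop("duplicate IDs in SMILES map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(smi)))
    stop("empty SMILES string for ID ", ids[!nzchar(smi)][1], call. = FALSE)
  structure(stats::setNames(smi, ids), class = "cpann_smiles_map")
}

#' Look up the SMILES for an identifier
#' @param map a `cpann_smiles_map` from [read_smiles_map()].
#' @param id object identifier.
#' @return the SMILES string, or `NULL` when the ID is absent.
#' @export
smiles_for <- function(map, id) {
  if (id %in% names(map)) unname(map[[id]]) else NULL
}
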