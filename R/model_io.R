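MODEL_MAGIC <- "CPANNR-MODEL 1"

#' Write a CPANN model to a plain-text file
#'
#' The dialect is a versioned text table: a magic line, header records (grid
#' dimensions, training parameters, variable counts), optional per-descriptor
#' normalization factors (present exactly when the model was trained on data
#' it normalized itself), a variable-name line, then one row per neuron
#' (row-major, x fastest) with the Kohonen weight block followed by the
#' output weight block, one column per variable.  Values are written at full
#' double precision so `read_cpann(write_cpann(m))` reproduces `m` exactly.
#'
#' @param model a [cpann()] model (trained or freshly initialized).
#' @param path output file; the conventional extension is `.unw`.
#' @export
write_cpann <- function(model, path) {
  g <- model$geometry
  cfg <- model$config
  hdr <- c(
    MODEL_MAGIC,
    paste("nx", g$nx, sep = "\t"),
    paste("ny", g$ny, sep = "\t"),
    paste("toroid", as.integer(g$toroid), sep = "\t"),
    paste("neighborhood", cfg$neighborhood, sep = "\t"),
    paste("max_radius", cfg$max_radius, sep = "\t"),
    paste("lr_max", fmt_num(cfg$lr_max), sep = "\t"),
    paste("lr_min", fmt_num(cfg$lr_min), sep = "\t"),
    paste("best_match", cfg$best_match, sep = "\t"),
    paste("epochs", cfg$epochs, sep = "\t"),
    paste("seed", cfg$seed, sep = "\t"),
    paste("trained", as.integer(isTRUE(model$trained)), sep = "\t"),
    paste("n_descriptors", length(model$descriptor_names), sep = "\t"),
    paste("n_targets", length(model$target_names), sep = "\t"),
    paste("normalizer", as.integer(!is.null(model$normalizer)), sep = "\t")
  )
  if (!is.null(model$normalizer)) {
    nz <- model$normalizer
    hdr <- c(hdr, vapply(seq_along(nz$descriptor_names), function(j) {
      paste("norm", nz$descriptor_names[j],
            fmt_num(nz$means[j]), fmt_num(nz$sds[j]), sep = "\t")
    }, character(1)))
  }
  hdr <- c(hdr, paste(c("variables", model$descriptor_names,
                        model$target_names), collapse = "\t"))
  wb <- cbind(model$kohonen, model$output)
  rows <- apply(wb, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

model_header_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "\t"), lines)
  if (!length(hit))
    stop("model file header is missing the '", key, "' record", call. = FALSE)
  strsplit(lines[hit[1]], "\t", fixed = TRUE)[[1]][-1]
}

#' Read a CPANN model file
#'
#' Reads the text dialect written by [write_cpann()]; see there for the
#' format.  Grid geometry, both weight blocks, the training configuration
#' and any embedded normalization factors are reconstructed, and the
#' variable names are available for the name-mismatch warning in
#' [predict.cpann()].
#'
#' @param path model file.
#' @return a `cpann` model.
#' @export
read_cpann <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != MODEL_MAGIC)
    stop("not a CPANN model file (missing header line)", call. = FALSE)
  nx <- as.integer(model_header_value(lines, "nx"))
  ny <- as.integer(model_header_value(lines, "ny"))
  toroid <- as.integer(model_header_value(lines, "toroid")) == 1
  cfg <- cpann_config(
    seed = as.integer(model_header_value(lines, "seed")),
    nx = nx, ny = ny, toroid = toroid,
    neighborhood = model_header_value(lines, "neighborhood"),
    max_radius = as.integer(model_header_value(lines, "max_radius")),
    lr_max = as.numeric(model_header_value(lines, "lr_max")),
    lr_min = as.numeric(model_header_value(lines, "lr_min")),
    best_match = model_header_value(lines, "best_match"),
    epochs = as.integer(model_header_value(lines, "epochs"))
  )
  trained <- as.integer(model_header_value(lines, "trained")) == 1
  k <- as.integer(model_header_value(lines, "n_descriptors"))
  m <- as.integer(model_header_value(lines, "n_targets"))
  has_nz <- as.integer(model_header_value(lines, "normalizer")) == 1

  nz <- NULL
  if (has_nz) {
    nl <- grep("^norm\t", lines, value = TRUE)
    if (length(nl) != k)
      stop("expected ", k, " normalization records, found ", length(nl),
           call. = FALSE)
    parts <- strsplit(nl, "\t", fixed = TRUE)
    nz <- structure(
      list(descriptor_names = vapply(parts, `[`, character(1), 2),
           means = as.numeric(vapply(parts, `[`, character(1), 3)),
           sds = as.numeric(vapply(parts, `[`, character(1), 4))),
      class = "cpann_normalizer"
    )
  }

  var_line <- grep("^variables\t", lines)
  if (length(var_line) != 1)
    stop("model file is missing the variable-name line", call. = FALSE)
  vars <- strsplit(lines[var_line], "\t", fixed = TRUE)[[1]][-1]
  if (length(vars) != k + m)
    stop("variable-name count (", length(vars),
         ") inconsistent with header (", k + m, ")", call. = FALSE)

  body <- lines[(var_line + 1):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) != nx * ny)
    stop("expected ", nx * ny, " weight rows, found ", length(body),
         call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != k + m)
  if (length(bad))
    stop("weight row ", bad[1], " has the wrong column count", call. = FALSE)
  wb <- matrix(as.numeric(unlist(fields)), nrow = nx * ny, ncol = k + m,
               byrow = TRUE)
  model <- structure(
    list(geometry = cfg$geometry,
         kohonen = structure(wb[, seq_len(k), drop = FALSE],
                             dimnames = list(NULL, vars[seq_len(k)])),
         output = structure(wb[, k + seq_len(m), drop = FALSE],
                            dimnames = list(NULL, if (m) vars[k + seq_len(m)])),
         descriptor_names = vars[seq_len(k)],
         target_names = if (m) vars[k + seq_len(m)] else character(0),
         config = cfg,
         normalizer = nz,
         trained = trained),
    class = "cpann"
  )
  model
}
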