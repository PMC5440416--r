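#' Generate a clustered synthetic dataset
#'
#' Draws well-separated Gaussian descriptor clusters with cluster-specific
#' target means — the structure under which "similar compounds excite the
#' same or similar neurons" holds by construction.  Cluster centres are
#' placed uniformly on a scaled hypercube and redrawn until every pairwise
#' centre distance is at least `separation` noise standard deviations; each
#' object's target is its cluster mean plus Gaussian noise.  Fully seeded:
#' the same spec gives a byte-identical dataset.
#'
#' @param n_clusters number of clusters.
#' @param per_cluster objects per cluster.
#' @param n_descriptors descriptor count.
#' @param separation minimal centre separation, in units of `noise_sd`.
#' @param noise_sd within-cluster descriptor noise standard deviation.
#' @param target_means per-cluster target means (default `1, 2, ...`).
#' @param target_noise_sd target noise standard deviation.
#' @param seed RNG seed.
#' @param name dataset label.
#' @return a [cpann_dataset()] with one target `tar.1` and class labels
#'   naming the cluster.
#' @export
generate_clustered <- function(n_clusters = 2, per_cluster = 10,
                               n_descriptors = 5, separation = 10,
                               noise_sd = 1, target_means = seq_len(n_clusters),
                               target_noise_sd = 0.1, seed = 1,
                               name = "synthetic") {
  stopifnot(separation > 0, noise_sd >= 0, target_noise_sd >= 0,
            length(target_means) == n_clusters)
  with_seed(seed, {
    # centre separation in units of the descriptor noise; absolute units
    # when the noise is zero (otherwise every centre would coincide)
    sep_abs <- separation * (if (noise_sd > 0) noise_sd else 1)
    side <- sep_abs * max(n_clusters, 2)
    repeat {
      centres <- matrix(stats::runif(n_clusters * n_descriptors, 0, side),
                        n_clusters, n_descriptors)
      if (n_clusters == 1) break
      d <- as.matrix(stats::dist(centres))
      if (min(d[upper.tri(d)]) >= sep_abs) break
    }
    n <- n_clusters * per_cluster
    cluster <- rep(seq_len(n_clusters), each = per_cluster)
    X <- centres[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n * n_descriptors, 0, noise_sd), n, n_descriptors)
    colnames(X) <- paste0("d", seq_len(n_descriptors))
    y <- target_means[cluster] + stats::rnorm(n, 0, target_noise_sd)
    cpann_dataset(ids = as.character(seq_len(n)),
                  descriptors = X,
                  targets = matrix(y, ncol = 1,
                                   dimnames = list(NULL, "tar.1")),
                  classes = paste0("C", cluster),
                  name = name)
  })
}

#' Split a dataset into training / internal test / external sets
#'
#' Stratified by class label: within each class, objects are assigned to the
#' splits in their original order, with per-class counts proportional to the
#' fractions (largest-remainder rounding), so each split's class proportions
#' stay within one object of the global ones.  IDs stay disjoint and the
#' union of the splits is the full set.
#'
#' @param ds a [cpann_dataset()].
#' @param fractions numeric length-3 vector (train, test, external) summing
#'   to 1.
#' @param withhold_external_targets blank the external set's targets (`NA`)
#'   to emulate untested compounds.
#' @return named list of three [cpann_dataset()]s: `train`, `test`,
#'   `external` (empty splits allowed only for zero fractions).
#' @export
generate_split <- function(ds, fractions = c(0.6, 0.2, 0.2),
                           withhold_external_targets = FALSE) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  n <- n_objects(ds)
  assign <- integer(n)
  for (cl in unique(ds$classes)) {
    idx <- which(ds$classes == cl)
    m <- length(idx)
    raw <- fractions * m
    cnt <- floor(raw)
    rem <- m - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    assign[idx] <- rep(1:3, times = cnt)
  }
  for (s in 1:3) {
    if (fractions[s] > 0 && !any(assign == s))
      stop("fraction ", fractions[s], " yields an empty split", call. = FALSE)
  }
  mk <- function(s, nm) {
    idx <- which(assign == s)
    if (!length(idx)) return(NULL)
    out <- subset_dataset(ds, idx, name = nm)
    if (s == 3 && withhold_external_targets && ncol(out$targets))
      out$targets[] <- NA_real_
    out
  }
  list(train = mk(1, "train"), test = mk(2, "test"),
       external = mk(3, "external"))
}

#' Hand-built winner-tie fixture
#'
#' A 2x1-grid model whose two neurons are exactly equidistant from a crafted
#' query object, to exercise the deterministic tie-break (lowest linear
#' index wins), plus that query as a one-object dataset.
#'
#' @return list with `model`, `dataset` (the query) and `query` (its
#'   descriptor vector).
#' @export
generate_tie_fixture <- function() {
  cfg <- cpann_config(seed = 1, nx = 2, ny = 1, max_radius = 0, epochs = 1)
  model <- cpann_init(cfg, c("d1", "d2"), "tar.1")
  model$kohonen <- matrix(c(0, 1,   # neuron (1,1)
                            2, 1),  # neuron (2,1)
                          nrow = 2, byrow = TRUE,
                          dimnames = list(NULL, c("d1", "d2")))
  model$output <- matrix(c(10, 20), nrow = 2,
                         dimnames = list(NULL, "tar.1"))
  model$trained <- TRUE
  query <- c(d1 = 1, d2 = 1)
  ds <- cpann_dataset(ids = "q1",
                      descriptors = matrix(query, nrow = 1,
                                           dimnames = list(NULL, c("d1", "d2"))),
                      targets = matrix(NA_real_, 1, 1,
                                       dimnames = list(NULL, "tar.1")),
                      name = "tie_query")
  list(model = model, dataset = ds, query = query)
}
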