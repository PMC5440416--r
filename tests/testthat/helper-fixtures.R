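# shared fixture builders and independent oracles used across test files

tiny_dataset <- function(n = 3, k = 2, m = 1, seed = 42, name = "tiny") {
  set.seed(seed)
  X <- matrix(round(rnorm(n * k), 6), n, k,
              dimnames = list(NULL, paste0("d", seq_len(k))))
  Y <- if (m) matrix(round(rnorm(n * m), 6), n, m,
                     dimnames = list(NULL, paste0("tar.", seq_len(m))))
  cpann_dataset(ids = as.character(seq_len(n)), descriptors = X,
                targets = Y, classes = rep(c("A", "B"), length.out = n),
                name = name)
}

# brute-force winner: scan every neuron, squared distance over given columns
oracle_winner <- function(W, x, cols = seq_len(ncol(W))) {
  d2 <- apply(W[, cols, drop = FALSE], 1,
              function(w) sum((w - x[cols])^2))
  list(index = which.min(d2), distance = sqrt(min(d2)))
}

# wrap-around Chebyshev distance oracle
oracle_topo <- function(a, b, nx, ny, toroid) {
  dx <- abs(a[1] - b[1]); dy <- abs(a[2] - b[2])
  if (toroid) { dx <- min(dx, nx - dx); dy <- min(dy, ny - dy) }
  max(dx, dy)
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# a trained model on the standard two-cluster fixture, shared where the
# exact training settings do not matter
fixture_model <- function(ds = generate_clustered(seed = 7)) {
  cpann(ds, cpann_config(seed = 11, nx = 3, ny = 3, max_radius = 2,
                         epochs = 30))
}

# inverse of render_topmap_text, used only to check the renderer
parse_topmap_text <- function(lines) {
  lapply(strsplit(lines, "|", fixed = TRUE), function(cells) {
    cells <- trimws(cells)
    lapply(cells, function(c) if (c == ".") character(0)
                              else strsplit(c, ",", fixed = TRUE)[[1]])
  })
}
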