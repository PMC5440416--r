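test_that("initialization is seeded and reproducible", {
  cfg <- cpann_config(seed = 1, nx = 4, ny = 3, max_radius = 2, epochs = 5)
  a <- cpann_init(cfg, paste0("d", 1:3), "tar.1")
  b <- cpann_init(cfg, paste0("d", 1:3), "tar.1")
  expect_identical(a$kohonen, b$kohonen)
  expect_identical(a$output, b$output)
  cfg2 <- cfg; cfg2$seed <- 2L
  c <- cpann_init(cfg2, paste0("d", 1:3), "tar.1")
  expect_false(identical(a$kohonen, c$kohonen))
  expect_true(all(a$kohonen >= 0 & a$kohonen <= 1))
})

test_that("topological distance matches the wrap-around oracle and is a metric", {
  for (toroid in c(FALSE, TRUE)) {
    g <- grid_geometry(9, 9, toroid)
    expect_equal(topological_distance(g, c(3, 4), c(3, 4)), 0)
    # corner to corner: 8 rings on the plane, 1 on the torus
    expect_equal(topological_distance(g, c(1, 1), c(9, 9)),
                 if (toroid) 1 else 8)
    set.seed(5)
    pts <- cbind(sample(1:9, 60, TRUE), sample(1:9, 60, TRUE))
    for (i in seq_len(20)) {
      a <- pts[i, ]; b <- pts[i + 20, ]; c <- pts[i + 40, ]
      dab <- topological_distance(g, a, b)
      expect_equal(dab, oracle_topo(a, b, 9, 9, toroid))
      expect_equal(dab, topological_distance(g, b, a))      # symmetry
      expect_equal(dab == 0, all(a == b))                   # identity
      expect_lte(dab, topological_distance(g, a, c) +       # triangle
                   topological_distance(g, c, b))
    }
  }
  expect_error(topological_distance(grid_geometry(3, 3), c(0, 1), c(1, 1)),
               "off the")
})

test_that("triangular neighbourhood factor has the stated linear form", {
  expect_equal(neighborhood_factor(0, 5), 1)
  expect_equal(neighborhood_factor(6, 5), 0)
  expect_equal(neighborhood_factor(1, 1), 0.5)
  expect_equal(neighborhood_factor(0:3, 2), c(1, 2/3, 1/3, 0))
  expect_error(neighborhood_factor(-1, 2), ">= 0")
})

test_that("winner search equals the brute-force argmin oracle", {
  m <- fixture_model()
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(5, sd = 10)
    w <- find_central_neuron(m, x)
    o <- oracle_winner(m$kohonen, x)
    expect_equal(w$index, o$index)
    expect_equal(w$distance, o$distance)
  }
  # masked search restricts the distance to the chosen columns
  for (i in 1:20) {
    x <- rnorm(5, sd = 10)
    w <- find_central_neuron(m, x, mask = c("d1", "d3"))
    o <- oracle_winner(m$kohonen, x, cols = c(1, 3))
    expect_equal(w$index, o$index)
  }
  expect_error(find_central_neuron(m, rep(0, 5), mask = integer(0)),
               "non-empty")
})

test_that("a neuron whose weights equal the query wins at distance zero", {
  m <- fixture_model()
  idx <- 5  # position (2,2) on the 3x3 grid
  w <- find_central_neuron(m, m$kohonen[idx, ])
  expect_equal(w$index, idx)
  expect_equal(unname(w$position), c(2, 2))
  expect_equal(w$distance, 0)
})

test_that("exact ties break to the lowest linear index, stably", {
  tf <- generate_tie_fixture()
  w1 <- find_central_neuron(tf$model, tf$query)
  w2 <- find_central_neuron(tf$model, tf$query)
  expect_equal(w1$index, 1)  # both neurons at distance 1; first index wins
  expect_identical(w1, w2)
  # nudging the query toward neuron 2 flips the winner
  w3 <- find_central_neuron(tf$model, tf$query + c(1e-9, 0))
  expect_equal(w3$index, 2)
})

test_that("a 1x1 network reproduces the scalar update-rule recursion", {
  # with a single neuron there is no winner search and no neighbourhood:
  # training must equal the plain recursion w <- w + eta_t (value - w),
  # simulated here independently with the same seeded start
  X <- c(0.2, 1.4, -0.6)
  Y <- c(2.0, 3.0, 1.0)
  ds <- cpann_dataset(ids = as.character(1:3),
                      descriptors = cbind(d1 = X),
                      targets = cbind(tar.1 = Y))
  cfg <- cpann_config(seed = 3, nx = 1, ny = 1, max_radius = 0,
                      lr_max = 0.3, lr_min = 0.05, epochs = 50)
  m <- cpann(ds, cfg)

  set.seed(cfg$seed)
  w <- runif(1, min(X), max(X))
  o <- runif(1, min(Y), max(Y))
  t_total <- cfg$epochs * 3
  t <- 0
  for (e in seq_len(cfg$epochs)) for (i in 1:3) {
    eta <- cfg$lr_max - (cfg$lr_max - cfg$lr_min) * t / (t_total - 1)
    w <- w + eta * (X[i] - w)
    o <- o + eta * (Y[i] - o)
    t <- t + 1
  }
  expect_equal(unname(m$kohonen[1, 1]), w, tolerance = 1e-12)
  expect_equal(unname(m$output[1, 1]), o, tolerance = 1e-12)
  # prediction from a 1x1 model is the single output weight for every object
  p <- predict(m, ds)
  expect_equal(p$table$pred.1, rep(unname(m$output[1, 1]), 3))
  # the recursion is a running average: the weight stays inside the data hull
  expect_gte(w, min(X)); expect_lte(w, max(X))
})

test_that("training is deterministic in (seed, data, config)", {
  ds <- generate_clustered(seed = 4, per_cluster = 5)
  cfg <- cpann_config(seed = 77, nx = 3, ny = 3, max_radius = 2, epochs = 15)
  m1 <- cpann(ds, cfg)
  m2 <- cpann(ds, cfg)
  expect_identical(m1$kohonen, m2$kohonen)
  expect_identical(m1$output, m2$output)
  cfg$seed <- 78L
  m3 <- cpann(ds, cfg)
  expect_false(identical(m1$kohonen, m3$kohonen))
})

test_that("well-separated clusters land on disjoint neurons with cluster-mean responses", {
  ds <- generate_clustered(n_clusters = 2, per_cluster = 8, seed = 21,
                           separation = 10, target_noise_sd = 0.1)
  m <- cpann(ds, cpann_config(seed = 9, nx = 3, ny = 3, max_radius = 2,
                              epochs = 40))
  p <- predict(m, ds)
  key <- paste(p$table$x, p$table$y)
  n1 <- unique(key[ds$classes == "C1"])
  n2 <- unique(key[ds$classes == "C2"])
  expect_length(intersect(n1, n2), 0)
  for (cl in c("C1", "C2")) {
    i <- ds$classes == cl
    spread <- diff(range(ds$targets[i, 1]))
    expect_lt(rmse(p$table$pred.1[i], ds$targets[i, 1]), spread)
  }
})

test_that("training a single neuron toward two targets approaches their mean", {
  # two compounds repeatedly exciting the same neuron: the converged output
  # weight is the running average of their endpoint values
  ds <- cpann_dataset(ids = c("t1", "t2"),
                      descriptors = cbind(d1 = c(0.5, 0.5)),
                      targets = cbind(tar.1 = c(2.19, 1.79)))
  cfg <- cpann_config(seed = 6, nx = 1, ny = 1, max_radius = 0,
                      lr_max = 0.4, lr_min = 0.005, epochs = 600)
  m <- cpann(ds, cfg)
  expect_equal(unname(m$output[1, 1]), mean(c(2.19, 1.79)),
               tolerance = 0.01)
})

test_that("full-vector best match uses targets during training only", {
  ds <- generate_clustered(seed = 14, per_cluster = 5)
  cfg <- cpann_config(seed = 2, nx = 3, ny = 3, max_radius = 2, epochs = 20,
                      best_match = "full_vector")
  m <- cpann(ds, cfg)
  expect_true(m$trained)
  # prediction-time winner is Kohonen-only: same result with targets blanked
  blank <- ds; blank$targets[] <- NA_real_
  p1 <- predict(m, ds); p2 <- predict(m, blank)
  expect_identical(p1$table[c("x", "y", "distance", "pred.1")],
                   p2$table[c("x", "y", "distance", "pred.1")])
})

test_that("predictions copy output weights exactly and masks behave", {
  ds <- generate_clustered(seed = 7, per_cluster = 4)
  m <- fixture_model(ds)
  p <- predict(m, ds)
  for (i in seq_len(n_objects(ds))) {
    idx <- position_index <- (p$table$y[i] - 1) * 3 + p$table$x[i]
    expect_identical(p$table$pred.1[i], unname(m$output[idx, 1]))
  }
  # the full mask is the identity
  pf <- predict(m, ds, mask = paste0("d", 1:5))
  expect_identical(p$table, pf$table)
  # perfect predictions give RMSE 0 and R 1
  perfect <- ds
  perfect$targets[, 1] <- p$table$pred.1
  ps <- predict(m, perfect)
  expect_equal(ps$summary$rmse, 0)
  expect_equal(ps$summary$r, 1)
})

test_that("missing target values train and score gracefully", {
  ds <- generate_clustered(seed = 10, per_cluster = 5)
  ds$targets[c(2, 9), 1] <- NA_real_
  m <- cpann(ds, cpann_config(seed = 1, nx = 3, ny = 3, max_radius = 2,
                              epochs = 20))
  p <- predict(m, ds)
  expect_equal(p$summary$n, n_objects(ds) - 2)
  expect_false(anyNA(p$table$pred.1))
})

test_that("top-maps partition the predicted objects", {
  ds <- generate_clustered(seed = 7)
  m <- fixture_model(ds)
  sets <- generate_split(ds, c(0.5, 0.3, 0.2))
  preds <- lapply(sets, function(s) predict(m, s))
  tm <- build_topmap(preds)
  expect_equal(nrow(tm$assignments), n_objects(ds))
  # every object sits in exactly one cell, at its prediction's neuron
  for (nm in names(sets)) {
    p <- preds[[nm]]
    for (i in seq_len(nrow(p$table))) {
      cell <- topmap_cell(tm, c(p$table$x[i], p$table$y[i]))
      expect_equal(sum(cell$id == p$table$id[i] & cell$dataset == nm), 1)
    }
  }
  # conservation: cell sizes sum to the object count
  sizes <- sum(vapply(seq_len(9), function(j) {
    pos <- c((j - 1) %% 3 + 1, (j - 1) %/% 3 + 1)
    nrow(topmap_cell(tm, pos))
  }, numeric(1)))
  expect_equal(sizes, n_objects(ds))
  # single prediction -> single non-empty cell
  one <- predict(m, ds[1])
  tm1 <- build_topmap(one)
  expect_equal(nrow(tm1$assignments), 1)
})

test_that("level plots index the weight blocks directly", {
  m <- fixture_model()
  g <- level_plot(m, "tar.1")
  expect_equal(dim(g), c(3, 3))
  for (x in 1:3) for (y in 1:3)
    expect_identical(g[x, y], unname(m$output[(y - 1) * 3 + x, 1]))
  gd <- level_plot(m, "d2")
  expect_identical(as.vector(gd), unname(m$kohonen[, 2]))
  expect_error(level_plot(m, "nope"), "valid names")
})

test_that("Euclidean distance maps are zero at the reference and symmetric", {
  m <- fixture_model()
  set.seed(2)
  for (i in 1:10) {
    a <- c(sample(1:3, 1), sample(1:3, 1))
    b <- c(sample(1:3, 1), sample(1:3, 1))
    ma <- euclidean_distance_map(m, a)
    mb <- euclidean_distance_map(m, b)
    expect_equal(ma[a[1], a[2]], 0)
    expect_equal(ma[b[1], b[2]], mb[a[1], a[2]])
  }
  dup <- m
  dup$kohonen[2, ] <- dup$kohonen[1, ]
  md <- euclidean_distance_map(dup, c(1, 1))
  expect_equal(md[2, 1], 0)
  expect_error(euclidean_distance_map(m, c(4, 1)), "off the")
})

test_that("continuous Tanimoto follows the stated formula", {
  expect_equal(continuous_tanimoto(c(2, 1, 3), c(2, 1, 3)), 1)
  expect_equal(continuous_tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(continuous_tanimoto(c(1, 0), c(1, 1)), 0.5)
  expect_error(continuous_tanimoto(c(0, 0), c(0, 0)), "undefined")
  expect_error(continuous_tanimoto(1:2, 1:3), "equal length")
})

test_that("Tanimoto maps agree with elementwise calls and flag degenerate cells", {
  m <- fixture_model()
  ref <- c(2, 2)
  tmap <- tanimoto_map(m, ref)
  expect_equal(tmap[2, 2], 1)
  w <- m$kohonen[4 + 1, ]  # linear index of (2,2) on 3x3 = 5
  for (x in 1:3) for (y in 1:3)
    expect_equal(tmap[x, y],
                 continuous_tanimoto(w, m$kohonen[(y - 1) * 3 + x, ]))
  z <- m
  z$kohonen[1, ] <- 0
  z$kohonen[5, ] <- 0   # reference and cell both zero -> undefined
  tz <- tanimoto_map(z, ref)
  expect_true(is.nan(tz[1, 1]))
})
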