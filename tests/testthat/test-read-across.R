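# a small hand-built map world used throughout this file:
# reference compounds (training/internal test) and one external query that
# share neurons by construction, via an untrained model whose neuron weights
# are placed by hand
ra_world <- function() {
  cfg <- cpann_config(seed = 1, nx = 3, ny = 3, max_radius = 0, epochs = 1)
  model <- cpann_init(cfg, c("d1", "d2"), "tar.1")
  pos <- cbind(x = rep(1:3, 3), y = rep(1:3, each = 3))
  model$kohonen <- cbind(d1 = as.numeric(pos[, 1]),
                         d2 = as.numeric(pos[, 2])) * 10
  model$output <- cbind(tar.1 = as.numeric(1:9))
  model$trained <- TRUE

  train <- cpann_dataset(
    ids = c("126", "26", "145", "200"),
    descriptors = cbind(d1 = c(10.2, 9.8, 20.1, 30.0),
                        d2 = c(10.1, 9.9, 10.0, 20.2)),
    targets = cbind(tar.1 = c(2.19, 1.79, 2.64, 5.00)),
    classes = c("phenol", "phenol", "phenol", "other"),
    name = "train")
  internal <- cpann_dataset(
    ids = c("301"),
    descriptors = cbind(d1 = 10.0, d2 = 9.7),
    targets = cbind(tar.1 = 2.00),
    name = "internal")
  external <- cpann_dataset(
    ids = c("7", "80"),
    descriptors = cbind(d1 = c(10.05, 29.5), d2 = c(10.05, 29.5)),
    targets = cbind(tar.1 = c(1.83, 4.10)),
    name = "external")

  sets <- list(train = train, internal = internal, external = external)
  preds <- lapply(sets, function(s) predict(model, s))
  list(model = model, sets = sets, preds = preds,
       topmap = build_topmap(preds))
}

test_that("objects are located at the cell that holds them", {
  w <- ra_world()
  pos <- locate_object(w$topmap, "7", dataset = "external")
  expect_equal(unname(pos), c(1, 1))
  cell <- topmap_cell(w$topmap, pos)
  expect_true("7" %in% cell$id)
  # compounds 126, 26, 301 share the query's neuron
  expect_setequal(cell$id, c("126", "26", "301", "7"))
  expect_error(locate_object(w$topmap, "nope"), "not found")
  one <- build_topmap(w$preds$internal)
  expect_equal(unname(locate_object(one, "301")), c(1, 1))
})

test_that("analogue search honours rings, exclusions and ordering", {
  w <- ra_world()
  # ring 0: the three co-located reference compounds, never the query set
  a0 <- find_analogues(w$topmap, w$sets, "7", "external", max_ring = 0)
  expect_setequal(a0$id, c("126", "26", "301"))
  expect_true(all(a0$ring == 0))
  expect_false("7" %in% a0$id)
  expect_false("80" %in% a0$id)
  # ordered by descriptor distance within the ring
  expect_equal(a0$id, a0$id[order(a0$descriptor_distance)])
  # ring 1 adds 145 (neuron (2,1)); expansion is a superset
  a1 <- find_analogues(w$topmap, w$sets, "7", "external", max_ring = 1)
  expect_true(all(a0$id %in% a1$id))
  expect_true("145" %in% a1$id)
  expect_equal(a1$ring[a1$id == "145"], 1)
  expect_equal(a1$id[seq_len(nrow(a0))], a0$id)  # ring-0 block first
  # a query alone on its neuron with max_ring 0 has no analogues
  alone <- find_analogues(w$topmap, w$sets, "80", "external", max_ring = 0)
  expect_equal(nrow(alone), 0)
})

test_that("analogues lacking the experimental value are dropped", {
  w <- ra_world()
  w$sets$train$targets[1, 1] <- NA_real_  # 126 untested now
  a <- find_analogues(w$topmap, w$sets, "7", "external", max_ring = 0)
  expect_false("126" %in% a$id)
})

test_that("equal-distance analogues rank deterministically by id", {
  w <- ra_world()
  # make 26 and 126 exactly equidistant from the query
  w$sets$train$descriptors[1, ] <- c(10.2, 10.2)
  w$sets$train$descriptors[2, ] <- c(9.9, 9.9)
  q <- w$sets$external$descriptors[1, ]
  d1 <- sqrt(sum((w$sets$train$descriptors[1, ] - q)^2))
  d2 <- sqrt(sum((w$sets$train$descriptors[2, ] - q)^2))
  expect_equal(d1, d2)
  a <- find_analogues(w$topmap, w$sets, "7", "external", max_ring = 0)
  tied <- a[a$descriptor_distance == d1, ]
  expect_equal(tied$id, sort(tied$id))
  a2 <- find_analogues(w$topmap, w$sets, "7", "external", max_ring = 0)
  expect_identical(a, a2)
})

test_that("read-across strategies reproduce the worked arithmetic", {
  an <- data.frame(dataset = "train", id = c("126", "26"),
                   class = "phenol", ring = c(0L, 0L),
                   descriptor_distance = c(0.1, 0.2),
                   exp = c(2.19, 1.79), stringsAsFactors = FALSE)
  expect_equal(predict_read_across(an, "nearest_analogue")$predicted, 2.19)
  expect_equal(predict_read_across(an, "analogue_mean")$predicted, 1.99)

  trend <- data.frame(dataset = "train", id = c("145", "126"),
                      class = "phenol", ring = 0L,
                      descriptor_distance = c(0.1, 0.2),
                      exp = c(2.64, 2.19), stringsAsFactors = FALSE)
  # endpoint regressed on methyl-group count, evaluated at zero methyls
  ra <- predict_read_across(trend, "local_trend", covariate = c(2, 1),
                            at = 0, covariate_name = "n_methyl")
  expect_equal(ra$predicted, 1.74)
  # prediction bounds: nearest is an element, mean lies inside the range
  expect_true(predict_read_across(an, "analogue_mean")$predicted >=
                min(an$exp))
  expect_true(predict_read_across(an, "analogue_mean")$predicted <=
                max(an$exp))
  expect_error(predict_read_across(an[0, ], "nearest_analogue"),
               "not possible")
  expect_error(predict_read_across(an[1, , drop = FALSE], "local_trend",
                                   covariate = 1, at = 0), "at least 2")
  expect_error(predict_read_across(an, "local_trend", covariate = c(1, 1),
                                   at = 0), "constant")
})

test_that("the batch workflow reports per-query analogue provenance", {
  w <- ra_world()
  ra <- read_across(w$preds$external, w$topmap, w$sets, max_ring = 1)
  t <- ra$table
  expect_equal(t$id, c("7", "80"))
  expect_true(all(t$possible))
  r7 <- t[t$id == "7", ]
  expect_equal(r7$ring, 0)
  expect_equal(r7$ra_pred, r7$analogue_exp)
  # ring-0 analogue count equals cell co-occupancy minus query-set members
  cell <- topmap_cell(w$topmap, c(r7$x, r7$y))
  expect_equal(sum(find_analogues(w$topmap, w$sets, "7", "external",
                                  max_ring = 0)$ring == 0),
               nrow(cell) - sum(cell$dataset == "external"))
})

test_that("manual overrides replay a recorded analogue selection", {
  w <- ra_world()
  auto <- read_across(w$preds$external, w$topmap, w$sets, max_ring = 1)
  forced <- read_across(w$preds$external, w$topmap, w$sets, max_ring = 1,
                        overrides = c("7" = "26"))
  expect_equal(forced$table$analogue_id[1], "26")
  expect_equal(forced$table$ra_pred[1], 1.79)
  expect_equal(forced$table[2, ], auto$table[2, ])  # others untouched
  # an override outside the analogue list is ignored, not invented
  ghost <- read_across(w$preds$external, w$topmap, w$sets, max_ring = 1,
                       overrides = c("7" = "200"))
  expect_equal(ghost$table$analogue_id[1], auto$table$analogue_id[1])
})

test_that("model and read-across errors are compared on the same set", {
  w <- ra_world()
  ra <- read_across(w$preds$external, w$topmap, w$sets, max_ring = 1)
  cmp <- compare_model_vs_readacross(ra)
  expect_equal(cmp$n, 2)
  expect_equal(cmp$rmse_readacross,
               rmse(ra$table$ra_pred, ra$table$exp))
  expect_equal(cmp$rmse_model,
               rmse(ra$table$model_pred, ra$table$exp))
  # exclusions apply to both errors before computation
  cmp1 <- compare_model_vs_readacross(ra, exclusions = "80")
  expect_equal(cmp1$n, 1)
  expect_equal(cmp1$rmse_model, abs(ra$table$model_pred[1] - ra$table$exp[1]))
  expect_equal(cmp1$rmse_readacross,
               abs(ra$table$ra_pred[1] - ra$table$exp[1]))
  # identical prediction vectors give identical RMSEs
  same <- ra
  same$table$ra_pred <- same$table$model_pred
  cs <- compare_model_vs_readacross(same)
  expect_equal(cs$rmse_model, cs$rmse_readacross)
  expect_error(compare_model_vs_readacross(ra, exclusions = c("7", "80")),
               "empty comparison")
})
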