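# toy feature samples: labels driven by low glucose, with some overlap noise
make_toy_samples <- function(n_series = 6L, per = 40L, seed = 31L,
                             pos_frac = 0.2) {
  set.seed(seed)
  rows <- lapply(seq_len(n_series), function(i) {
    lab <- rbinom(per, 1, pos_frac)
    cgm <- ifelse(lab == 1, rnorm(per, 75, 8), rnorm(per, 140, 25))
    data.frame(series_id = sprintf("S%02d", i), meal_index = 1L,
               t = seq_len(per), cgm = cgm,
               rig = abs(rnorm(per, 0.8, 0.4)),
               grc = rnorm(per, ifelse(lab == 1, -1.5, 0), 0.7),
               label = lab, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

toy_meta <- function(samples) {
  ids <- unique(samples$series_id)
  data.frame(series_id = ids, patient_id = ids, stringsAsFactors = FALSE)
}

test_that("the false-negative cost is the exact negative:positive ratio", {
  expect_equal(compute_fn_cost(c(rep(0, 32), rep(1, 2)))$cost_fn, 16)
  expect_equal(compute_fn_cost(c(rep(0, 10), rep(1, 10)))$cost_fn, 1)
  expect_error(compute_fn_cost(rep(0, 5)), "no positive")

  set.seed(901)
  for (i in 1:50) {
    n1 <- sample(1:50, 1)
    n0 <- sample(0:500, 1)
    labels <- sample(c(rep(0, n0), rep(1, n1)))
    expect_identical(compute_fn_cost(labels)$cost_fn, n0 / n1)
  }
})

test_that("cross-subject folds partition patients without leakage", {
  meta <- data.frame(series_id = sprintf("S%02d", 1:12),
                     patient_id = sprintf("P%02d", c(1:10, 3, 7)))
  folds <- cross_subject_folds(meta, k = 5, seed = 5)
  expect_length(folds, 5L)
  # each fold's test side holds 2 patients (10 patients round-robin into 5)
  expect_true(all(vapply(folds, function(f) length(f$test_patients), 0L) == 2L))
  # partition: every series in exactly one test fold
  all_test <- unlist(lapply(folds, `[[`, "test_series"))
  expect_setequal(all_test, meta$series_id)
  expect_equal(length(all_test), length(unique(all_test)))
  for (f in folds) {
    expect_length(intersect(f$train_patients, f$test_patients), 0L)
    # dual-series patients are co-located
    pat_of_test <- meta$patient_id[meta$series_id %in% f$test_series]
    expect_length(intersect(pat_of_test,
                            meta$patient_id[meta$series_id %in% f$train_series]),
                  0L)
  }
  # determinism
  expect_identical(folds, cross_subject_folds(meta, k = 5, seed = 5))
  expect_error(cross_subject_folds(meta[1:3, ], k = 5), "at least k")
})

test_that("grid search minimizes inner cost-weighted loss with stable ties", {
  samples <- make_toy_samples()
  meta <- toy_meta(samples)
  cost <- compute_fn_cost(samples$label)

  # single-point grid returns immediately
  g1 <- data.frame(k = 7L)
  expect_equal(grid_search("knn", samples, meta, g1, cost = cost), g1)

  # a k = 1 neighbor on near-separable data beats a degenerate huge k
  grid <- data.frame(k = c(1000L, 3L))
  best <- grid_search("knn", samples, meta, grid, cost = cost, seed = 2)
  expect_equal(best$k, 3L)
  expect_length(attr(best, "inner_loss"), 2L)

  # exact ties break by declared grid order
  tie_grid <- data.frame(k = c(5L, 5L))
  best <- grid_search("knn", samples, meta, tie_grid, cost = cost, seed = 2)
  expect_identical(rownames(best), "1")
})

test_that("all families train, score in [0,1], and respect the 0.5 cut", {
  samples <- make_toy_samples()
  cost <- compute_fn_cost(samples$label)
  grids <- single_point_grids()
  for (fam in names(grids)) {
    model <- train_model(fam, samples, cost, grids[[fam]], seed = 3)
    pred <- predict(model, samples)
    expect_true(all(pred$score >= 0 & pred$score <= 1), info = fam)
    expect_identical(pred$label, as.integer(pred$score >= 0.5), info = fam)
    expect_gt(roc_auc(samples$label, pred$score), 0.8)
  }
  expect_error(train_model("boosted_stump", samples, cost,
                           data.frame(x = 1)))
})

test_that("a linear SVM separates a separable toy set exactly", {
  toy <- data.frame(series_id = "S1", meal_index = 1L, t = 1:4,
                    cgm = c(60, 65, 150, 160), rig = c(0, 0, 1, 1),
                    grc = c(-1, -1, 1, 1), label = c(1, 1, 0, 0))
  model <- train_model("svm_ln", toy, compute_fn_cost(toy$label),
                       data.frame(C = 10))
  expect_identical(predict(model, toy)$label, as.integer(toy$label))
})

test_that("1-NN reproduces its training set and duplicates of positives", {
  samples <- make_toy_samples(n_series = 3L, per = 25L)
  model <- train_model("knn", samples, compute_fn_cost(samples$label),
                       data.frame(k = 1L))
  pred <- predict(model, samples)
  expect_identical(pred$label, samples$label)
  dup <- samples[samples$label == 1, ][1, ]
  expect_equal(predict(model, dup)$label, 1L)
})

test_that("raising the false-negative cost does not lose recall", {
  # heavily overlapping classes: without cost weighting the rare positives
  # are swamped by the majority, so the weighting must move the boundary
  make_overlap <- function(n_series, seed) {
    set.seed(seed)
    rows <- lapply(seq_len(n_series), function(i) {
      per <- 80L
      lab <- rbinom(per, 1, 0.07)
      data.frame(series_id = sprintf("O%02d", i), meal_index = 1L,
                 t = seq_len(per),
                 cgm = ifelse(lab == 1, rnorm(per, 110, 18), rnorm(per, 130, 22)),
                 rig = rnorm(per, 1, 0.5),
                 grc = ifelse(lab == 1, rnorm(per, -0.6, 0.8), rnorm(per, 0, 0.8)),
                 label = lab, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  train <- make_overlap(8L, seed = 41L)
  test <- make_overlap(3L, seed = 42L)
  base_cost <- compute_fn_cost(train$label)
  cheap <- base_cost
  cheap$cost_fn <- 1
  hyper <- data.frame(num_trees = 200L, max_depth = 0L)
  recall_of <- function(cost) {
    m <- train_model("rf", train, cost, hyper, seed = 6)
    p <- predict(m, test)
    sum(test$label == 1 & p$label == 1) / sum(test$label == 1)
  }
  expect_gte(recall_of(base_cost), recall_of(cheap))
})

test_that("prediction validates columns and handles empty input", {
  samples <- make_toy_samples(n_series = 3L)
  model <- train_model("lr", samples, compute_fn_cost(samples$label),
                       data.frame(C = 1))
  expect_error(predict(model, samples[, c("series_id", "cgm", "grc")]),
               "feature column")
  out <- predict(model, samples[0, ])
  expect_equal(nrow(out), 0L)
  expect_named(out, c("score", "label"))

  # ablated models need only cgm and grc
  m2 <- train_model("lr", samples, compute_fn_cost(samples$label),
                    data.frame(C = 1), feature_subset = "cgm_grc")
  expect_silent(predict(m2, samples[, c("series_id", "cgm", "grc")]))
})
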