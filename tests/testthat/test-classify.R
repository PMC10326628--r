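test_that("the 4:1 split is stratified, sample-grouped and deterministic", {
  m <- toy_manifest(100, 5)
  sp <- make_split(m, ratio = 0.8, seed = 2)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), unique(m$sample_id))
  # stratification: 10 test samples per label
  lab <- unique(m[, c("sample_id", "label")])
  expect_equal(sum(lab$label[lab$sample_id %in% sp$test] == "pregnancy"), 10)
  # same seed, same plan
  expect_identical(make_split(m, 0.8, seed = 2), sp)
  expect_false(identical(make_split(m, 0.8, seed = 3)$test, sp$test))
})

test_that("no sample's replicates ever straddle the partitions", {
  # exhaustive audit over a small manifest and many seeds
  m <- toy_manifest(10, 5)
  for (seed in 1:25) {
    sp <- make_split(m, 0.8, seed = seed)
    side <- ifelse(m$sample_id %in% sp$train, "train", "test")
    per_sample <- tapply(side, m$sample_id, function(v) length(unique(v)))
    expect_true(all(per_sample == 1))
  }
  expect_error(make_split(m[m$label == "pregnancy", ], 0.8, 1),
               "stratification error")
})

test_that("a one-point grid reduces to a single cross-validated fit", {
  d <- separable_scores(n_samples = 40, seed = 71)
  spec <- classifier_spec("svm", grid = data.frame(kernel = "linear",
                                                   cost = 1, gamma = NA),
                          cv_folds = 4, seed = 1)
  model <- grid_search_cv(spec, d$x, d$labels, d$groups)
  expect_equal(nrow(model$cv_table), 1)
  expect_true(is.finite(model$cv_accuracy))
  expect_error(classifier_spec("svm", grid = data.frame()), "empty")
})

test_that("every algorithm separates linearly separable scores in CV", {
  d <- separable_scores(n_samples = 60, p = 20, shift = 3, seed = 72,
                        mode = "all")
  grids <- list(
    svm = data.frame(kernel = "linear", cost = 1, gamma = NA),
    rf = data.frame(ntree = 100, nodesize = 1, maxnodes = NA),
    xgboost = data.frame(nrounds = 60, max_depth = 3, eta = 0.3,
                         subsample = 1),
    cnn1d = data.frame(conv_layers = 1, kernels = 8))
  for (algo in names(grids)) {
    spec <- classifier_spec(algo, grid = grids[[algo]], cv_folds = 3,
                            seed = 7, cnn_epochs = 40)
    model <- grid_search_cv(spec, d$x, d$labels, d$groups)
    expect_gte(model$cv_accuracy, 0.95)
    # training data through its own model: near-perfect
    p <- predict(model, d$x)
    expect_gte(mean(p$predicted == d$labels), 0.95)
    expect_equal(p$p_pregnancy + p$p_non_pregnancy, rep(1, nrow(p)),
                 tolerance = 1e-6)
  }
})

test_that("permuted labels give chance-level CV accuracy", {
  d <- separable_scores(n_samples = 40, p = 10, seed = 73)
  accs <- sapply(1:10, function(r) {
    set.seed(100 + r)
    lab <- sample(d$labels)
    spec <- classifier_spec("svm", grid = data.frame(kernel = "linear",
                                                     cost = 1, gamma = NA),
                            cv_folds = 4, seed = r)
    grid_search_cv(spec, d$x, lab, d$groups)$cv_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("grid selection uses mean CV accuracy with first-listed tie-breaks", {
  d <- separable_scores(n_samples = 40, p = 10, seed = 74)
  grid <- data.frame(kernel = c("linear", "linear"), cost = c(1, 1),
                     gamma = c(NA, NA))
  spec <- classifier_spec("svm", grid = grid, cv_folds = 4, seed = 1)
  model <- grid_search_cv(spec, d$x, d$labels, d$groups)
  # identical grid points tie; the first must win
  expect_identical(rownames(model$best_params), "1")
})

test_that("inference is deterministic and shape-checked", {
  d <- separable_scores(n_samples = 40, p = 10, seed = 75)
  spec <- classifier_spec("rf", grid = data.frame(ntree = 100, nodesize = 1,
                                                  maxnodes = NA),
                          cv_folds = 3, seed = 4)
  model <- grid_search_cv(spec, d$x, d$labels, d$groups)
  x2 <- rbind(d$x[1, , drop = FALSE], d$x[1, , drop = FALSE])
  p <- predict(model, x2)
  expect_identical(p$p_pregnancy[1], p$p_pregnancy[2])
  expect_identical(p$predicted[1], p$predicted[2])
  expect_error(predict(model, d$x[, 1:5]), "shape error")
})

test_that("majority vote aggregates replicate predictions per sample", {
  preds <- data.frame(
    p_pregnancy = c(0.9, 0.8, 0.4, 0.2, 0.3, 0.6),
    p_non_pregnancy = c(0.1, 0.2, 0.6, 0.8, 0.7, 0.4),
    predicted = c("pregnancy", "pregnancy", "non_pregnancy",
                  "non_pregnancy", "non_pregnancy", "pregnancy"),
    stringsAsFactors = FALSE)
  agg <- aggregate_by_sample(preds, c("A", "A", "A", "B", "B", "B"))
  expect_equal(agg$predicted, c("pregnancy", "non_pregnancy"))
  expect_equal(agg$votes_pregnancy, c(2, 1))
  # a 1-1 tie resolves to non_pregnancy
  agg2 <- aggregate_by_sample(preds[c(1, 3), ], c("C", "C"))
  expect_equal(agg2$predicted, "non_pregnancy")
})
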