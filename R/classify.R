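#' Sample-grouped stratified train/test split
#'
#' Splits at the sample level (all replicate spectra of a sample land on the
#' same side -- labels are clinical outcomes of samples, and replicate
#' leakage would inflate test accuracy), stratified by outcome so each
#' partition's label proportions match the cohort within one sample.
#'
#' @param manifest Cohort manifest (one or more rows per sample).
#' @param ratio Training fraction (default 0.8, i.e. the 4:1 design).
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return Object of class `split_plan` with `train` and `test` sample id
#'   vectors.
#' @export
make_split <- function(manifest, ratio = 0.8, seed = 1) {
  validate_manifest(manifest)
  samples <- unique(manifest[, c("sample_id", "label")])
  if (anyNA(samples$label)) stop("stratification error: unlabeled samples")
  tab <- table(factor(samples$label, levels = outcome_levels()))
  if (any(tab < 2)) {
    stop("stratification error: need >= 2 samples per label, got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  set.seed(seed)
  test <- character(0)
  for (g in outcome_levels()) {
    ids <- samples$sample_id[samples$label == g]
    n_test <- max(1L, round(length(ids) * (1 - ratio)))
    test <- c(test, sample(ids, n_test))
  }
  structure(list(train = sort(setdiff(samples$sample_id, test)),
                 test = sort(test), ratio = ratio, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test samples (ratio %.2f, seed %d)\n",
              length(x$train), length(x$test), x$ratio, x$seed))
  invisible(x)
}

#' Default hyperparameter grid per algorithm
#'
#' The grids cover the tunables that matter for each family: kernels,
#' penalty and kernel parameter for the SVM; tree count, node size and tree
#' size for the random forest; rounds, depth, learning rate and subsampling
#' for XGBoost; convolution depth and kernel count for the 1D CNN. `NA` for
#' the SVM `gamma` means the library default (1/n features); `NA` for the
#' forest `maxnodes` means unlimited tree size.
#'
#' @param algorithm One of `"cnn1d"`, `"svm"`, `"rf"`, `"xgboost"`.
#' @return A data frame, one row per grid point.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    svm = expand.grid(kernel = c("radial", "linear"), cost = c(0.1, 1, 10),
                      gamma = c(NA, 0.01, 0.001),
                      stringsAsFactors = FALSE),
    rf = expand.grid(ntree = c(100, 300), nodesize = c(1, 5),
                     maxnodes = c(NA, 32)),
    xgboost = expand.grid(nrounds = c(100, 300), max_depth = c(3, 6),
                          eta = c(0.1, 0.3), subsample = c(0.8, 1.0)),
    cnn1d = expand.grid(conv_layers = c(1, 2), kernels = c(8, 16, 32)),
    stop("unknown algorithm: ", algorithm))
}

#' Specification of one classifier family
#'
#' @param algorithm `"cnn1d"`, `"svm"`, `"rf"` or `"xgboost"`.
#' @param grid Hyperparameter grid (data frame, one row per candidate);
#'   defaults to [default_grid()].
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment and every stochastic
#'   fit.
#' @param cnn_epochs,cnn_batch Training budget for the CNN backend.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("cnn1d", "svm", "rf", "xgboost"),
                            grid = NULL, cv_folds = 5, seed = 1,
                            cnn_epochs = 40, cnn_batch = 32) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("configuration error: empty hyperparameter grid")
  if (cv_folds < 2) stop("configuration error: cv_folds must be >= 2")
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 cnn_epochs = as.integer(cnn_epochs),
                 cnn_batch = as.integer(cnn_batch)),
            class = "classifier_spec")
}

fit_backend <- function(spec, params, x, y, seed) {
  y <- factor(as.character(y), levels = outcome_levels())
  set.seed(seed)
  switch(spec$algorithm,
    svm = {
      gamma <- if (is.na(params$gamma)) 1 / ncol(x) else params$gamma
      e1071::svm(x, y, kernel = as.character(params$kernel),
                 cost = params$cost, gamma = gamma, probability = TRUE)
    },
    rf = {
      maxnodes <- if (is.na(params$maxnodes)) NULL else params$maxnodes
      randomForest::randomForest(x, y, ntree = params$ntree,
                                 nodesize = params$nodesize,
                                 maxnodes = maxnodes)
    },
    xgboost = {
      # second factor level is the positive class in the xgboost interface
      yf <- factor(as.character(y), levels = rev(outcome_levels()))
      xgboost::xgboost(x, yf, nrounds = params$nrounds,
                       max_depth = params$max_depth,
                       learning_rate = params$eta,
                       subsample = params$subsample,
                       nthread = 1, verbosity = 0, seed = seed)
    },
    cnn1d = train_cnn(x, y, conv_layers = params$conv_layers,
                      kernels = params$kernels, epochs = spec$cnn_epochs,
                      batch_size = spec$cnn_batch, seed = seed))
}

predict_backend <- function(spec, fit, x) {
  lev <- outcome_levels()
  p <- switch(spec$algorithm,
    svm = {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      pr[, lev, drop = FALSE]
    },
    rf = {
      pr <- stats::predict(fit, x, type = "prob")
      pr[, lev, drop = FALSE]
    },
    xgboost = {
      p1 <- stats::predict(fit, x)  # probability of the positive (pregnancy) level
      cbind(p1, 1 - p1)
    },
    cnn1d = predict_cnn(fit, x))
  colnames(p) <- lev
  rownames(p) <- NULL
  p
}

#' Grid-search cross-validation training
#'
#' Exhaustive evaluation of the spec's hyperparameter grid by group-aware
#' stratified k-fold cross-validation: folds are formed over samples, never
#' over spectra, so replicates of one sample are always on the same side of
#' every fold. The grid point with the highest mean CV accuracy wins (ties
#' broken by grid order); the winner is refit on all training data.
#'
#' @param spec A [classifier_spec()].
#' @param scores Feature matrix (training spectra in rows, e.g. PCA scores).
#' @param labels Outcome label per spectrum.
#' @param groups Sample id per spectrum (grouping unit for the folds).
#' @return Object of class `raman_classifier` with the fitted backend, the
#'   selected grid point and the CV table.
#' @export
grid_search_cv <- function(spec, scores, labels, groups) {
  stopifnot(inherits(spec, "classifier_spec"))
  scores <- as.matrix(scores)
  labels <- factor(as.character(labels), levels = outcome_levels())
  if (anyNA(labels)) stop("labels outside the two-class outcome set")
  groups <- as.character(groups)
  stopifnot(nrow(scores) == length(labels), length(labels) == length(groups))

  ug <- unique(groups)
  samples <- data.frame(group = ug, label = labels[match(ug, groups)],
                        stringsAsFactors = FALSE)
  set.seed(spec$seed)
  fold_of <- integer(nrow(samples)); names(fold_of) <- samples$group
  for (g in outcome_levels()) {
    ids <- sample(samples$group[samples$label == g])
    if (length(ids)) {
      fold_of[ids] <- rep_len(seq_len(spec$cv_folds), length(ids))
    }
  }
  fold <- fold_of[groups]
  if (length(unique(fold)) < 2) {
    stop("configuration error: degenerate folds (too few samples per fold)")
  }

  cv <- spec$grid
  cv$cv_accuracy <- NA_real_
  for (gidx in seq_len(nrow(spec$grid))) {
    params <- spec$grid[gidx, , drop = FALSE]
    accs <- numeric(0)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2 || !any(!tr)) next
      fit <- fit_backend(spec, params, scores[tr, , drop = FALSE], labels[tr],
                         seed = spec$seed + f)
      p <- predict_backend(spec, fit, scores[!tr, , drop = FALSE])
      hard <- hard_label(p)
      accs <- c(accs, mean(hard == as.character(labels[!tr])))
    }
    cv$cv_accuracy[gidx] <- mean(accs)
  }
  best <- which.max(cv$cv_accuracy)   # ties -> first grid point
  fit <- fit_backend(spec, spec$grid[best, , drop = FALSE], scores, labels,
                     seed = spec$seed)
  structure(list(spec = spec, algorithm = spec$algorithm, fit = fit,
                 best_params = spec$grid[best, , drop = FALSE],
                 cv_accuracy = cv$cv_accuracy[best], cv_table = cv,
                 n_features = ncol(scores), levels = outcome_levels()),
            class = "raman_classifier")
}

## argmax with ties resolved to non_pregnancy (the conservative call)
hard_label <- function(prob) {
  ifelse(prob[, "pregnancy"] > prob[, "non_pregnancy"],
         "pregnancy", "non_pregnancy")
}

#' @export
print.raman_classifier <- function(x, ...) {
  cat(sprintf("<raman_classifier:%s> %d features, CV accuracy %.3f\n",
              x$algorithm, x$n_features, x$cv_accuracy))
  cat("best grid point:\n")
  print(x$best_params, row.names = FALSE)
  invisible(x)
}

#' @export
summary.raman_classifier <- function(object, ...) {
  cat(sprintf("Classifier family : %s\n", object$algorithm))
  cat(sprintf("Features          : %d\n", object$n_features))
  cat(sprintf("CV folds          : %d\n", object$spec$cv_folds))
  cat(sprintf("Best CV accuracy  : %.3f\n", object$cv_accuracy))
  cat("CV table:\n")
  print(object$cv_table, row.names = FALSE)
  invisible(object)
}

#' Predict outcome probabilities and labels
#'
#' @param object A trained [grid_search_cv()] classifier.
#' @param scores Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Data frame with `p_pregnancy`, `p_non_pregnancy` (summing to 1)
#'   and `predicted` (argmax; exact ties resolve to `non_pregnancy`).
#' @export
predict.raman_classifier <- function(object, scores, ...) {
  scores <- as.matrix(scores)
  if (ncol(scores) != object$n_features) {
    stop("shape error: ", ncol(scores), " features but the model was trained",
         " on ", object$n_features)
  }
  p <- predict_backend(object$spec, object$fit, scores)
  data.frame(p_pregnancy = p[, "pregnancy"],
             p_non_pregnancy = p[, "non_pregnancy"],
             predicted = hard_label(p),
             stringsAsFactors = FALSE)
}

#' Majority vote over a sample's replicate predictions
#'
#' @param predictions Output of [predict.raman_classifier()].
#' @param sample_ids Sample id per prediction row.
#' @return Data frame with one row per sample: vote counts and the majority
#'   label (ties resolve to `non_pregnancy`).
#' @export
aggregate_by_sample <- function(predictions, sample_ids) {
  sample_ids <- as.character(sample_ids)
  stopifnot(nrow(predictions) == length(sample_ids))
  ids <- unique(sample_ids)
  votes_p <- vapply(ids, function(id)
    sum(predictions$predicted[sample_ids == id] == "pregnancy"), numeric(1))
  votes_n <- vapply(ids, function(id)
    sum(predictions$predicted[sample_ids == id] == "non_pregnancy"), numeric(1))
  data.frame(sample_id = ids, votes_pregnancy = votes_p,
             votes_non_pregnancy = votes_n,
             predicted = ifelse(votes_p > votes_n, "pregnancy",
                                "non_pregnancy"),
             stringsAsFactors = FALSE, row.names = NULL)
}
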